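# ggplot2 visualizations for the result objects.

#' Plot per-class evaluation metrics
#'
#' Bar panel of precision, recall and F1 per taste class.
#'
#' @param object A `taste_metrics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taste_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_class,
                            cols = c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$class, y = .data$value, fill = .data$class)) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~metric) +
    labs(x = NULL, y = NULL,
         title = sprintf("Per-class metrics (accuracy %.3f, support %.0f%%)",
                         object$accuracy, 100 * object$support_fraction)) +
    theme_minimal()
}

#' Plot a token-level attribution heatmap
#'
#' One bar per SMILES token in sequence order, signed by contribution
#' toward the target label (positive supports, negative detracts).
#'
#' @param object A `taste_attribution` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taste_attribution <- function(object, ...) {
  df <- object$tokens
  df$pos <- seq_len(nrow(df))
  ggplot(df, aes(x = factor(.data$pos), y = .data$score, fill = .data$score)) +
    geom_col() +
    scale_fill_gradient2(low = "firebrick", mid = "grey90", high = "forestgreen") +
    ggplot2::scale_x_discrete(labels = df$token) +
    labs(x = "SMILES token", y = "attribution",
         title = sprintf("Integrated gradients toward \"%s\"",
                         object$target_label),
         subtitle = object$smiles) +
    theme_minimal()
}

#' Plot a curation report
#'
#' Removal counts per cascade stage.
#'
#' @param object A `curation_report` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.curation_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[!df$stage %in% c("input", "output"), ]
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot(df, aes(x = .data$stage, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "records removed",
         title = sprintf("Curation: %d in, %d out", object$n_input,
                         object$n_output)) +
    theme_minimal()
}
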