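# Evaluation suite for imbalanced five-class taste prediction: confusion
# matrix, per-class precision/recall/F1, accuracy, macro (unweighted) and
# class-frequency-weighted averages, one-vs-rest AUROC (midrank
# Mann-Whitney), support-aware scoring under abstention, binary-task
# reduction, and the multi-label probability-threshold analysis.

#' Confusion matrix over the five taste classes
#'
#' @param y_true,y_pred Vectors of taste labels (character or factor).
#' @return 5x5 integer matrix; entry (i, j) counts true class i predicted
#'   as class j. Row sums are the class counts.
#' @export
taste_confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have the same length",
          class = "tastekit_eval_error")
  }
  t_ <- taste_label(as.character(y_true))
  p_ <- taste_label(as.character(y_pred))
  m <- table(true = t_, predicted = p_)
  matrix(as.integer(m), 5, 5, dimnames = list(true = taste_labels(),
                                              predicted = taste_labels()))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' One-vs-rest definitions: precision is the proportion of predicted-class
#' molecules that truly belong to the class, recall the proportion of true
#' class members that were predicted as such. A 0/0 ratio (class never
#' predicted, never true, or both) is reported as 0 and flagged in the
#' `flagged` column.
#'
#' @param cm 5x5 confusion matrix from [taste_confusion()].
#' @return Tibble with columns `class`, `n` (true instances), `precision`,
#'   `recall`, `f1`, `flagged`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == 5, ncol(cm) == 5, all(cm >= 0))
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(tp, pred_n)
  recall <- safe_div(tp, true_n)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  tibble(
    class = taste_labels(),
    n = as.integer(true_n),
    precision = unname(precision),
    recall = unname(recall),
    f1 = unname(f1),
    flagged = unname(pred_n == 0 | true_n == 0)
  )
}

#' Macro (unweighted) average of a per-class metric
#'
#' The arithmetic mean over classes, `sum(M_i) / C`. Emphasizes minority
#' classes: a model cannot offset poor umami performance with good sweet
#' performance.
#'
#' @param values Numeric vector of per-class metric values.
#' @return Real.
#' @export
macro_average <- function(values) {
  if (!length(values)) {
    abort("macro_average needs at least one value", class = "tastekit_eval_error")
  }
  sum(values) / length(values)
}

#' Class-frequency-weighted average of a per-class metric
#'
#' `sum((n_i / N) * M_i)` with `n_i` the instance count of class i and `N`
#' the total count. Equals the macro average when counts are uniform.
#'
#' @param values Numeric vector of per-class metric values.
#' @param counts Non-negative instance counts, not all zero.
#' @return Real.
#' @export
weighted_average <- function(values, counts) {
  stopifnot(length(values) == length(counts), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) {
    abort("weighted_average needs at least one instance",
          class = "tastekit_eval_error")
  }
  sum(counts / n * values)
}

#' One-vs-rest AUROC per class
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling: for each
#' class, the predicted class probability scores class membership against
#' the rest. Classes without both a positive and a negative instance are
#' skipped (`NA`, flagged), not fatal.
#'
#' @param y_true Vector of true taste labels.
#' @param probs Matrix of class probabilities, columns in `taste_labels()`
#'   order.
#' @return Tibble with `class`, `auroc`, `flagged`; the macro average over
#'   scored classes is in attribute `"macro"` and via [macro_average()].
#' @export
ovr_auroc <- function(y_true, probs) {
  t_ <- taste_label(as.character(y_true))
  stopifnot(nrow(probs) == length(t_), ncol(probs) == 5)
  res <- numeric(5); flag <- logical(5)
  for (i in 1:5) {
    pos <- as.integer(t_) == i
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      res[i] <- NA_real_; flag[i] <- TRUE
      next
    }
    r <- rank(probs[, i])  # midranks for ties
    res[i] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out <- tibble(class = taste_labels(), auroc = res, flagged = flag)
  attr(out, "macro") <- macro_average(res[!flag])
  out
}

#' Binary-task reduction of multi-class predictions
#'
#' Collapses all non-positive classes into one negative class and scores
#' the resulting binary task. Any correct five-class prediction remains
#' correct after collapsing, so binary accuracy is always at least the
#' multi-class accuracy. Abstentions (`NA` predictions) are excluded from
#' the scored set; their share is reported as `support`.
#'
#' @param y_true Vector of true taste labels.
#' @param y_pred Vector of predicted labels, `NA` for abstentions.
#' @param positive_class The class scored as positive.
#' @param probs Optional probability matrix (columns in label order) for
#'   the AUROC of the positive class; `NA` otherwise.
#' @return One-row tibble: `positive_class`, `n` (scored), `support`,
#'   `accuracy`, `precision`, `recall`, `f1`, `auroc`.
#' @export
binary_reduction <- function(y_true, y_pred, positive_class, probs = NULL) {
  positive_class <- as.character(positive_class)
  stopifnot(positive_class %in% taste_labels())
  keep <- !is.na(y_pred)
  support <- mean(keep)
  yt <- as.character(y_true)[keep] == positive_class
  yp <- as.character(y_pred)[keep] == positive_class
  tp <- sum(yt & yp); fp <- sum(!yt & yp); fn <- sum(yt & !yp)
  acc <- mean(yt == yp)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  auroc <- NA_real_
  if (!is.null(probs)) {
    pcol <- probs[keep, taste_label_index(positive_class) + 1L]
    n1 <- sum(yt); n0 <- sum(!yt)
    if (n1 > 0 && n0 > 0) {
      r <- rank(pcol)
      auroc <- (sum(r[yt]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  tibble(positive_class = positive_class, n = sum(keep), support = support,
         accuracy = acc, precision = precision, recall = recall, f1 = f1,
         auroc = auroc)
}

#' Multi-label analysis under a probability threshold
#'
#' For molecules carrying several true labels, every class with probability
#' strictly above `threshold` (default 0.2, the uniform-distribution level
#' over five classes) counts as predicted. Each molecule is categorized
#' mutually exclusively: `exact` (predicted set equals the true set),
#' `too_many` (strict superset), `collapsed` (a single predicted label
#' despite multiple true ones; `collapsed_correct` when that label is in
#' the true set), or none of these.
#'
#' @param probs Probability matrix, one row per molecule.
#' @param true_labels List of character vectors, each with >= 2 true labels.
#' @param threshold Strict probability cutoff (default 0.2).
#' @return Object of class `multilabel_outcome` with counts `n_total`,
#'   `n_exact`, `n_too_many`, `n_collapsed`, `n_collapsed_correct` and a
#'   per-molecule `detail` tibble.
#' @export
multilabel_eval <- function(probs, true_labels, threshold = 0.2) {
  stopifnot(nrow(probs) == length(true_labels))
  lv <- taste_labels()
  cat_ <- character(nrow(probs))
  correct_ <- logical(nrow(probs))
  pred_sets <- character(nrow(probs))
  for (i in seq_len(nrow(probs))) {
    pred <- lv[probs[i, ] > threshold]
    truth <- unique(as.character(true_labels[[i]]))
    pred_sets[i] <- paste(pred, collapse = "+")
    cat_[i] <- if (setequal(pred, truth)) {
      "exact"
    } else if (length(pred) == 1) {
      correct_[i] <- pred %in% truth
      "collapsed"
    } else if (all(truth %in% pred) && length(pred) > length(truth)) {
      "too_many"
    } else {
      "other"
    }
  }
  structure(list(
    n_total = nrow(probs),
    n_exact = sum(cat_ == "exact"),
    n_too_many = sum(cat_ == "too_many"),
    n_collapsed = sum(cat_ == "collapsed"),
    n_collapsed_correct = sum(correct_),
    threshold = threshold,
    detail = tibble(category = cat_, predicted = pred_sets,
                    collapsed_correct = correct_)
  ), class = "multilabel_outcome")
}

#' @export
print.multilabel_outcome <- function(x, ...) {
  cat(sprintf("Multi-label analysis (p > %.2g) over %d molecules\n",
              x$threshold, x$n_total))
  cat(sprintf("  exact: %d  too many: %d  collapsed: %d (of which correct: %d)\n",
              x$n_exact, x$n_too_many, x$n_collapsed, x$n_collapsed_correct))
  invisible(x)
}

#' Evaluate a model on a held-out test set
#'
#' Computes the full metric table: per-class precision/recall/F1 and
#' one-vs-rest AUROC, overall accuracy, macro and weighted averages, and
#' support. With `confidence` settings (a list with `k`, `threshold`,
#' `seed`), predictions go through the consensus rule; abstained molecules
#' are excluded from accuracy and the per-class metrics but counted in
#' support.
#'
#' @param model A `taste_model`.
#' @param test Tibble with `smiles` (or `canonical_smiles`) and `label`,
#'   disjoint from the training molecules.
#' @param confidence `NULL`, or `list(k = 10, threshold = 10, seed = 1)`.
#' @return Object of class `taste_metrics`.
#' @export
evaluate_model <- function(model, test, confidence = NULL) {
  if (nrow(test) == 0) {
    abort("test set is empty", class = "tastekit_eval_error")
  }
  smiles <- .training_smiles(test)
  y_true <- taste_label(as.character(test$label))
  if (is.null(confidence)) {
    probs <- predict_proba(model, smiles)
    y_pred <- factor(taste_labels()[apply(probs, 1, which.max)],
                     levels = taste_labels())
    accepted <- rep(TRUE, length(y_pred))
  } else {
    k <- confidence$k %||% 10L
    thr <- confidence$threshold %||% k
    seed <- confidence$seed %||% 1L
    cons <- consensus_predict_many(model, smiles, k = k, threshold = thr,
                                   seed = seed)
    accepted <- vapply(cons, function(r) r$accepted, NA)
    y_pred <- factor(
      vapply(cons, function(r) as.character(r$accepted_label), ""),
      levels = taste_labels()
    )
    probs <- do.call(rbind, lapply(cons, function(r) r$mean_proba))
  }
  if (!any(accepted)) {
    abort("all molecules abstained; nothing to score",
          class = "tastekit_eval_error")
  }
  cm <- taste_confusion(y_true[accepted], y_pred[accepted])
  pc <- per_class_metrics(cm)
  au <- ovr_auroc(y_true[accepted], probs[accepted, , drop = FALSE])
  pc$auroc <- au$auroc
  macro <- list(
    precision = macro_average(pc$precision),
    recall = macro_average(pc$recall),
    f1 = macro_average(pc$f1),
    auroc = attr(au, "macro")
  )
  scored <- !au$flagged
  weighted <- list(
    precision = weighted_average(pc$precision, pc$n),
    recall = weighted_average(pc$recall, pc$n),
    f1 = weighted_average(pc$f1, pc$n),
    auroc = if (any(scored)) weighted_average(au$auroc[scored], pc$n[scored]) else NA_real_
  )
  structure(list(
    n_classes = 5L,
    confusion = cm,
    per_class = pc,
    accuracy = sum(diag(cm)) / sum(cm),
    macro = macro,
    weighted = weighted,
    support_fraction = mean(accepted),
    n_total = length(y_true),
    n_scored = sum(accepted),
    confidence = confidence
  ), class = "taste_metrics")
}

#' @export
print.taste_metrics <- function(x, ...) {
  cat(sprintf("Evaluation over %d molecules (%d scored, support %.1f%%)\n",
              x$n_total, x$n_scored, 100 * x$support_fraction))
  cat(sprintf("  accuracy: %.4f\n", x$accuracy))
  cat(sprintf("  macro    P %.4f  R %.4f  F1 %.4f  AUROC %s\n",
              x$macro$precision, x$macro$recall, x$macro$f1,
              ifelse(is.na(x$macro$auroc), "NA", sprintf("%.4f", x$macro$auroc))))
  cat(sprintf("  weighted P %.4f  R %.4f  F1 %.4f\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1))
  invisible(x)
}

#' @rdname evaluate_model
#' @param x A `taste_metrics` object.
#' @param ... Unused.
#' @export
tidy.taste_metrics <- function(x, ...) {
  x$per_class
}

#' @rdname evaluate_model
#' @export
glance.taste_metrics <- function(x, ...) {
  tibble(
    accuracy = x$accuracy,
    macro_precision = x$macro$precision,
    macro_recall = x$macro$recall,
    macro_f1 = x$macro$f1,
    macro_auroc = x$macro$auroc,
    weighted_f1 = x$weighted$f1,
    support = x$support_fraction,
    n = x$n_total
  )
}
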