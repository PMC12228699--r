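# Integrated-gradients attribution. The generic routine integrates the
# gradient of a scalar scoring function along the straight path from a
# baseline input to the input at hand (midpoint Riemann rule); the
# molecule-level wrapper runs it on the token model's input embeddings,
# sums per-dimension attributions within each token, and maps atom-bearing
# tokens onto atoms.

#' Integrated gradients for a scalar scoring function
#'
#' Computes, per input feature, `(x_i - baseline_i)` times the average
#' gradient of `f` along the straight path from `baseline` to `x`,
#' discretized at `n_steps` midpoints. For a linear scorer with zero
#' baseline the result is exactly `w_i * x_i` at any step count; the
#' completeness property `sum(attr) = f(x) - f(baseline)` holds up to the
#' discretization error, which shrinks as `n_steps` grows.
#'
#' @param f Scalar-valued function of `x`.
#' @param x Numeric vector or matrix input.
#' @param baseline Baseline input of the same shape (default: zero).
#' @param n_steps Path discretization (default 64, minimum 2).
#' @param grad_fn Optional gradient function of `f` (same shape as `x`).
#'   When omitted, central finite differences are used.
#' @return Attribution array of the same shape as `x`.
#' @export
integrated_gradients <- function(f, x, baseline = NULL, n_steps = 64L,
                                 grad_fn = NULL) {
  if (is.null(baseline)) baseline <- x * 0
  if (!identical(dim(x), dim(baseline)) || length(x) != length(baseline)) {
    abort("baseline must have the same shape as x",
          class = "tastekit_attribution_error")
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 2) {
    abort("n_steps must be at least 2", class = "tastekit_attribution_error")
  }
  if (is.null(grad_fn)) grad_fn <- function(z) .numeric_grad(f, z)
  diffs <- x - baseline
  acc <- x * 0
  for (j in seq_len(n_steps)) {
    alpha <- (j - 0.5) / n_steps
    g <- grad_fn(baseline + alpha * diffs)
    if (any(!is.finite(g))) {
      abort("non-finite gradient along the integration path",
            class = "tastekit_attribution_error")
    }
    acc <- acc + g
  }
  diffs * acc / n_steps
}

# central finite differences, elementwise
.numeric_grad <- function(f, x, eps = 1e-4) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

#' Completeness gap of an integrated-gradients attribution
#'
#' Returns `|sum(attributions) - (f(x) - f(baseline))|`, a numerical quality
#' diagnostic for the path discretization: it is zero for linear scorers
#' and shrinks toward zero as `n_steps` increases.
#'
#' @inheritParams integrated_gradients
#' @return Non-negative real.
#' @export
completeness_gap <- function(f, x, baseline = NULL, n_steps = 64L,
                             grad_fn = NULL) {
  if (is.null(baseline)) baseline <- x * 0
  attr_ <- integrated_gradients(f, x, baseline, n_steps, grad_fn)
  abs(sum(attr_) - (f(x) - f(baseline)))
}

#' Per-atom attribution for a token-model prediction
#'
#' Runs integrated gradients on the token model's input representation
#' (token embeddings plus positions; zero baseline by default), sums each
#' token's per-dimension attributions into a token score, and maps
#' atom-bearing tokens onto atoms. Positive scores support the target
#' label, negative scores detract from it. Attribution mass on structural
#' tokens (bonds, ring digits, parentheses) is accumulated in
#' `residual_nonatom` so that atom scores plus residual recover the total
#' attribution mass.
#'
#' Only the token backend has a gradient path; tree-based models raise an
#' unsupported-backend error.
#'
#' @param model A `taste_model` with backend `"token_lm"`.
#' @param smiles A single valid SMILES string.
#' @param target_label Taste label to attribute toward.
#' @param n_steps Path discretization (default 64).
#' @param against `"logit"` (default) differentiates the raw class logit,
#'   `"probability"` the softmax output.
#' @return Object of class `taste_attribution`: list with `smiles`,
#'   `target_label`, `atom_scores` (one signed score per atom),
#'   `residual_nonatom`, `tokens` (tibble of token, atom, score), and the
#'   completeness diagnostics `total_attribution` and `score_delta`
#'   (`f(x) - f(baseline)`).
#' @export
atom_attributions <- function(model, smiles, target_label, n_steps = 64L,
                              against = c("logit", "probability")) {
  stopifnot(inherits(model, "taste_model"), length(smiles) == 1)
  against <- match.arg(against)
  if (model$backend != "token_lm") {
    abort(paste0("backend \"", model$backend,
                 "\" has no gradient path; atom attribution requires the ",
                 "token_lm backend"),
          class = "tastekit_unsupported_backend")
  }
  if (!is_valid_smiles(smiles)) {
    abort(paste0("cannot parse SMILES: ", encodeString(smiles, quote = "\"")),
          class = "tastekit_parse_error")
  }
  target_idx <- taste_label_index(as.character(target_label)) + 1L
  tokens <- tokenize_smiles(smiles)
  x <- .tlm_input_rep(model$fit, smiles)
  scorer <- .tlm_scorer(model$fit, target_idx, against = against)
  attr_ <- integrated_gradients(scorer$value, x, baseline = x * 0,
                                n_steps = n_steps, grad_fn = scorer$grad)
  token_scores <- rowSums(attr_)
  n_atoms <- max(tokens$atom, 0, na.rm = TRUE)
  atom_scores <- numeric(n_atoms)
  is_atom <- !is.na(tokens$atom)
  atom_scores[tokens$atom[is_atom]] <- token_scores[is_atom]
  tokens$score <- token_scores
  structure(list(
    smiles = smiles,
    target_label = as.character(target_label),
    atom_scores = atom_scores,
    residual_nonatom = sum(token_scores[!is_atom]),
    tokens = tokens,
    total_attribution = sum(token_scores),
    score_delta = scorer$value(x) - scorer$value(x * 0),
    n_steps = n_steps,
    against = against
  ), class = "taste_attribution")
}

#' @export
print.taste_attribution <- function(x, ...) {
  cat(sprintf("Atom attribution toward \"%s\" for %s\n",
              x$target_label, x$smiles))
  top <- order(x$atom_scores, decreasing = TRUE)[seq_len(min(3, length(x$atom_scores)))]
  cat("  top atoms:", paste0("#", top, " (", sprintf("%+.3f", x$atom_scores[top]), ")",
                             collapse = ", "), "\n")
  cat(sprintf("  residual on structural tokens: %+.4f\n", x$residual_nonatom))
  invisible(x)
}

#' @rdname atom_attributions
#' @param x A `taste_attribution`.
#' @param ... Unused.
#' @export
tidy.taste_attribution <- function(x, ...) {
  x$tokens
}

#' Export an attribution as a JSON sidecar
#'
#' Writes the per-atom scores (and the token table) to JSON; scores
#' round-trip exactly. Rendering a shaded 2D depiction is left to external
#' drawing tools -- the sidecar carries everything they need.
#'
#' @param attr A `taste_attribution`.
#' @param path Output path.
#' @return `invisible(path)`.
#' @export
export_heatmap <- function(attr, path) {
  stopifnot(inherits(attr, "taste_attribution"))
  payload <- list(
    smiles = attr$smiles,
    target_label = attr$target_label,
    atom_scores = attr$atom_scores,
    residual_nonatom = attr$residual_nonatom,
    tokens = attr$tokens$token,
    token_scores = attr$tokens$score,
    token_atom = attr$tokens$atom
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
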