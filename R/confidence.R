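# Test-time-augmentation consensus: predict over k synonymous SMILES of the
# same molecule and accept the modal label only when its vote count reaches
# the agreement threshold; otherwise abstain. With the default strict
# threshold (threshold = k) all variants must agree unanimously.

#' Consensus prediction with abstention
#'
#' Draws `k` synonymous SMILES for the molecule, predicts each, and votes on
#' the argmax labels. The modal label is accepted iff its multiplicity
#' reaches `threshold` and the mode is unique; a tied mode abstains
#' (conservative). Backends whose features are invariant to the SMILES form
#' (the tree models) always reach unanimity.
#'
#' @param model A `taste_model`.
#' @param smiles A single valid SMILES string.
#' @param k Ensemble size (default 10).
#' @param threshold Required agreement count, `1 <= threshold <= k`
#'   (default `k`: strict unanimity).
#' @param seed Seed for the variant draws.
#' @return Object of class `taste_consensus`: list with
#'   `per_variant_labels`, `accepted` (logical), `accepted_label` (factor,
#'   `NA` on abstention), `agreement`, `k`, `threshold`, and the averaged
#'   probability vector `mean_proba`.
#' @export
consensus_predict <- function(model, smiles, k = 10L, threshold = k, seed = 1L) {
  stopifnot(length(smiles) == 1)
  res <- consensus_predict_many(model, smiles, k = k, threshold = threshold,
                                seed = seed)
  res[[1]]
}

#' Consensus predictions for many molecules
#'
#' Vectorized form of [consensus_predict()]; one variant-generation batch
#' and one prediction batch for the whole input.
#'
#' @inheritParams consensus_predict
#' @param smiles Character vector of valid SMILES.
#' @return List of `taste_consensus` objects.
#' @export
consensus_predict_many <- function(model, smiles, k = 10L, threshold = k,
                                   seed = 1L) {
  k <- as.integer(k)
  if (threshold < 1 || threshold > k) {
    abort("threshold must lie between 1 and k", class = "tastekit_consensus_error")
  }
  ok <- is_valid_smiles(smiles)
  if (!all(ok)) {
    abort(paste0("cannot parse SMILES: ",
                 encodeString(smiles[!ok][1], quote = "\"")),
          class = "tastekit_parse_error")
  }
  canon <- canonicalize_smiles(smiles)
  aug <- .augment_batch(canon, k = k, seed = seed)
  probs <- predict_proba(model, aug$variant_smiles, .validate = FALSE)
  idx <- apply(probs, 1, which.max)
  labels <- factor(taste_labels()[idx], levels = taste_labels())
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    sel <- aug$parent == i
    li <- labels[sel]
    v <- .vote(li, threshold)
    out[[i]] <- structure(list(
      smiles = smiles[i],
      per_variant_labels = li,
      accepted = v$accepted,
      accepted_label = v$label,
      agreement = v$agreement,
      k = k,
      threshold = as.integer(threshold),
      mean_proba = colMeans(probs[sel, , drop = FALSE])
    ), class = "taste_consensus")
  }
  out
}

# the voting rule: accept the modal label iff its multiplicity reaches the
# threshold and the mode is unique; a tied mode abstains
.vote <- function(labels, threshold) {
  votes <- table(factor(labels, levels = taste_labels()))
  agreement <- max(votes)
  modal <- names(votes)[votes == agreement]
  accepted <- agreement >= threshold && length(modal) == 1
  list(
    accepted = accepted,
    label = factor(if (accepted) modal else NA_character_,
                   levels = taste_labels()),
    agreement = as.integer(agreement)
  )
}

#' @export
print.taste_consensus <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("consensus: %s (%d/%d agree, threshold %d)\n",
                as.character(x$accepted_label), x$agreement, x$k, x$threshold))
  } else {
    cat(sprintf("consensus: ABSTAIN (max agreement %d/%d, threshold %d)\n",
                x$agreement, x$k, x$threshold))
  }
  invisible(x)
}

#' @rdname consensus_predict
#' @param x A `taste_consensus`.
#' @param ... Unused.
#' @export
tidy.taste_consensus <- function(x, ...) {
  tibble(
    smiles = x$smiles,
    accepted = x$accepted,
    accepted_label = as.character(x$accepted_label),
    agreement = x$agreement,
    k = x$k,
    threshold = x$threshold
  )
}

#' Support: the fraction of consensus results with a prediction
#'
#' Support is the share of evaluated molecules that received a non-abstained
#' label under the consensus rule.
#'
#' @param results List of `taste_consensus` objects.
#' @return Real in `[0, 1]`.
#' @export
support_fraction <- function(results) {
  if (!length(results)) {
    abort("support_fraction needs at least one consensus result",
          class = "tastekit_consensus_error")
  }
  mean(vapply(results, function(r) r$accepted, NA))
}
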