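# Curation filter cascade, deduplication, reporting and leakage-safe
# splitting. Filters run in a fixed order -- invalid -> multi-fragment ->
# charged -> overweight -> duplicate -- so each removed record is attributed
# to exactly one stage in the report.

# per-record structural properties needed by the cascade; smiles assumed valid
.record_props <- function(smiles) {
  graphs <- parse_molecules(smiles, strict = TRUE)
  tibble(
    n_fragments = map_int(graphs, "n_fragments"),
    any_charged = map_lgl(graphs, function(g) any(g$charge != 0))
  )
}

#' Remove records with invalid SMILES
#'
#' @param records Tibble with a `smiles` column.
#' @return List with elements `kept` and `removed`, both tibbles; the order
#'   of kept rows is preserved.
#' @export
filter_invalid <- function(records) {
  ok <- is_valid_smiles(records$smiles)
  list(kept = records[ok, , drop = FALSE], removed = records[!ok, , drop = FALSE])
}

#' Remove records with multiple uncharged fragments
#'
#' Drops entries whose molecular graph has two or more fragments, all of
#' them uncharged -- typically a tastant recorded together with a solvent.
#' Salt pairs written as charged fragments are left to the charge filter.
#'
#' @param records Tibble of valid-SMILES records.
#' @return List with `kept` and `removed` tibbles.
#' @export
filter_multifragment <- function(records) {
  if (nrow(records) == 0) return(list(kept = records, removed = records))
  props <- .record_props(records$smiles)
  drop <- props$n_fragments >= 2 & !props$any_charged
  list(kept = records[!drop, , drop = FALSE], removed = records[drop, , drop = FALSE])
}

#' Remove records containing formally charged atoms
#'
#' Charged entries are excluded to prevent substances with missing counter
#' ions from entering the dataset; any formal charge on any atom (including
#' net-neutral zwitterions) triggers removal.
#'
#' @param records Tibble of valid-SMILES records.
#' @return List with `kept` and `removed` tibbles.
#' @export
filter_charged <- function(records) {
  if (nrow(records) == 0) return(list(kept = records, removed = records))
  props <- .record_props(records$smiles)
  drop <- props$any_charged
  list(kept = records[!drop, , drop = FALSE], removed = records[drop, , drop = FALSE])
}

#' Remove records at or above a molecular-weight cutoff
#'
#' Keeps molecules strictly below `max_da` Daltons (default 2000 Da, chosen
#' so SMILES strings stay within a small language model's context window);
#' ties at the boundary are removed. Adds/refreshes a `mol_weight_da`
#' column on the kept records.
#'
#' @param records Tibble of valid-SMILES records.
#' @param max_da Weight cutoff in Daltons.
#' @return List with `kept` and `removed` tibbles.
#' @export
filter_weight <- function(records, max_da = 2000) {
  if (nrow(records) == 0) return(list(kept = records, removed = records))
  mw <- molecular_weight(records$smiles)
  records$mol_weight_da <- mw
  drop <- mw >= max_da
  list(kept = records[!drop, , drop = FALSE], removed = records[drop, , drop = FALSE])
}

#' Collapse duplicate (canonical SMILES, label) rows
#'
#' Rows with identical canonical SMILES *and* identical label collapse to
#' one, the first occurrence's source winning. Rows sharing a canonical
#' SMILES but carrying different labels are retained as distinct rows --
#' that is the dataset's convention for multi-taste molecules such as
#' bittersweet compounds.
#'
#' @param records Tibble with a `canonical_smiles` column (see
#'   [standardize_records()]).
#' @return List with `kept` tibble and `removed_count`.
#' @export
deduplicate_records <- function(records) {
  if (nrow(records) == 0) return(list(kept = records, removed_count = 0L))
  stopifnot("canonical_smiles" %in% names(records))
  key <- paste(records$canonical_smiles, as.character(records$label), sep = "\r")
  keep <- !duplicated(key)
  list(kept = records[keep, , drop = FALSE],
       removed_count = sum(!keep))
}

#' Standardize records
#'
#' Adds a `canonical_smiles` column (the pinned canonical form, a fixed
#' point of canonicalization) and a `mol_weight_da` column when missing.
#' Records must already be valid.
#'
#' @param records Tibble with `smiles`.
#' @return The records with derived columns added.
#' @export
standardize_records <- function(records) {
  records$canonical_smiles <- canonicalize_smiles(records$smiles)
  if (!"mol_weight_da" %in% names(records)) {
    records$mol_weight_da <- molecular_weight(records$smiles)
  }
  records
}

#' Curate a molecule--taste dataset
#'
#' Runs the full cascade in fixed order: invalid -> multiple uncharged
#' fragments -> charged atoms -> molecular weight -> canonical-SMILES
#' deduplication, optionally applying out-of-band label corrections (a data
#' frame of `canonical_smiles`, `label`) before deduplication. The returned
#' report attributes every removed record to exactly one stage and satisfies
#' `n_input = n_output + sum(removed)`.
#'
#' @param records Tibble with `smiles`, `label`, optional `source`.
#' @param max_da Molecular-weight cutoff in Daltons (strictly-below rule).
#' @param corrections Optional data frame mapping `canonical_smiles` to a
#'   corrected `label`, applied before deduplication.
#' @return Object of class `taste_curation`: list with `records` (curated
#'   tibble, standardized) and `report` (class `curation_report`).
#' @export
curate <- function(records, max_da = 2000, corrections = NULL) {
  records <- as_tibble(records)
  n_input <- nrow(records)
  s1 <- filter_invalid(records)
  s2 <- filter_multifragment(s1$kept)
  s3 <- filter_charged(s2$kept)
  s4 <- filter_weight(s3$kept, max_da = max_da)
  kept <- s4$kept
  if (nrow(kept)) {
    kept <- standardize_records(kept)
  } else {
    kept$canonical_smiles <- character(0)
    if (!"mol_weight_da" %in% names(kept)) kept$mol_weight_da <- numeric(0)
  }
  if (!is.null(corrections) && nrow(kept)) {
    stopifnot(all(c("canonical_smiles", "label") %in% names(corrections)))
    m <- match(kept$canonical_smiles, corrections$canonical_smiles)
    hit <- !is.na(m)
    if (any(hit)) {
      kept$label[hit] <- taste_label(as.character(corrections$label[m[hit]]))
    }
  }
  s5 <- deduplicate_records(kept)
  report <- structure(list(
    n_input = n_input,
    removed_invalid = nrow(s1$removed),
    removed_multifragment = nrow(s2$removed),
    removed_charged = nrow(s3$removed),
    removed_overweight = nrow(s4$removed),
    removed_duplicate = s5$removed_count,
    n_output = nrow(s5$kept)
  ), class = "curation_report")
  structure(list(records = s5$kept, report = report), class = "taste_curation")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report\n")
  cat(sprintf("  input rows:          %d\n", x$n_input))
  cat(sprintf("  removed invalid:     %d\n", x$removed_invalid))
  cat(sprintf("  removed multi-frag:  %d\n", x$removed_multifragment))
  cat(sprintf("  removed charged:     %d\n", x$removed_charged))
  cat(sprintf("  removed overweight:  %d\n", x$removed_overweight))
  cat(sprintf("  removed duplicate:   %d\n", x$removed_duplicate))
  cat(sprintf("  output rows:         %d\n", x$n_output))
  invisible(x)
}

#' @export
print.taste_curation <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' @rdname curate
#' @param x A `curation_report` or `taste_curation` object.
#' @param ... Unused.
#' @export
tidy.curation_report <- function(x, ...) {
  tibble(
    stage = c("input", "invalid", "multifragment", "charged", "overweight",
              "duplicate", "output"),
    n = c(x$n_input, x$removed_invalid, x$removed_multifragment,
          x$removed_charged, x$removed_overweight, x$removed_duplicate,
          x$n_output)
  )
}

#' @export
tidy.taste_curation <- function(x, ...) tidy(x$report)

#' Leakage-safe train/test split
#'
#' Groups rows by canonical SMILES before assignment so multi-label
#' duplicates of a molecule always land in the same partition, then assigns
#' a seeded random subset of molecule groups to the test set. No canonical
#' SMILES ever occurs on both sides.
#'
#' @param records Curated tibble with `canonical_smiles`.
#' @param test_fraction Fraction of unique molecules held out (in (0,1)).
#' @param seed Integer seed for the shuffle.
#' @return Object of class `taste_split`: list with `train`, `test`,
#'   `test_fraction`, `seed`.
#' @export
split_dataset <- function(records, test_fraction = 0.15, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must lie strictly between 0 and 1",
          class = "tastekit_split_error")
  }
  if (!"canonical_smiles" %in% names(records)) {
    records <- standardize_records(records)
  }
  mols <- unique(records$canonical_smiles)
  n_test <- max(1L, round(test_fraction * length(mols)))
  test_mols <- withr::with_seed(seed, sample(mols, n_test))
  in_test <- records$canonical_smiles %in% test_mols
  structure(list(
    train = records[!in_test, , drop = FALSE],
    test = records[in_test, , drop = FALSE],
    test_fraction = test_fraction,
    seed = seed
  ), class = "taste_split")
}

#' @export
print.taste_split <- function(x, ...) {
  cat(sprintf(
    "Train/test split: %d train rows, %d test rows (%.0f%% of molecules held out, seed %d)\n",
    nrow(x$train), nrow(x$test), 100 * x$test_fraction, x$seed
  ))
  invisible(x)
}
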