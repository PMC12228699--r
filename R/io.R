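# Dataset file I/O. The on-disk format is a UTF-8 comma-separated file with
# a header and one label per row; molecules carrying several tastes appear
# as duplicated rows with different labels.

#' Read a molecule--taste dataset from CSV
#'
#' Expects columns `smiles` and `label` (case-insensitive), optionally
#' `source`, `canonical_smiles` and `mol_weight_da`. Labels outside the
#' closed five-class vocabulary are an error naming the first offending row;
#' in particular "salty" is rejected -- salty compounds must be re-labeled
#' `undefined` upstream, not silently accepted.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `smiles`, `label` (factor), `source`, and
#'   any optional columns present.
#' @export
read_taste_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read dataset: no such file ", path),
          class = "tastekit_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  names(df) <- tolower(names(df))
  missing <- setdiff(c("smiles", "label"), names(df))
  if (length(missing)) {
    abort(paste0("dataset is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tastekit_io_error")
  }
  df <- as_tibble(df)
  if (nrow(df) == 0) {
    df$label <- taste_label(character(0))
    if (!"source" %in% names(df)) df$source <- character(0)
    return(df)
  }
  df$label <- taste_label(df$label, rows = seq_len(nrow(df)) + 1L)  # +1: header
  if (!"source" %in% names(df)) df$source <- NA_character_
  df$smiles <- as.character(df$smiles)
  df
}

#' Write a molecule--taste dataset to CSV
#'
#' Inverse of [read_taste_csv()]: a write followed by a read round-trips the
#' records exactly. Derived columns (`canonical_smiles`, `mol_weight_da`)
#' are written when present.
#'
#' @param records Tibble or data frame with at least `smiles` and `label`.
#' @param path Output path.
#' @return `invisible(path)`.
#' @export
write_taste_csv <- function(records, path) {
  stopifnot(all(c("smiles", "label") %in% names(records)))
  keep <- intersect(
    c("smiles", "label", "source", "canonical_smiles", "mol_weight_da"),
    names(records)
  )
  out <- as.data.frame(records[, keep, drop = FALSE])
  out$label <- as.character(out$label)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}
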