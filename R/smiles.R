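# SMILES validity, canonicalization and synonymous-SMILES enumeration.
#
# All conversions go through OpenBabel (ChemmineOB). Batch calls carry a
# numeric title per input line and use OpenBabel's continue-on-error mode, so
# invalid entries are detected by their absence from the output rather than
# aborting the batch.

.OB_ERR_OPT <- data.frame(names = "e", args = "", stringsAsFactors = FALSE)

# one batched format conversion; returns output lines (SMILES formats) or
# raw text (SDF)
.ob_convert <- function(from, to, input) {
  out <- suppressWarnings(ChemmineOB::convertFormat(
    from, to, input,
    options = .OB_ERR_OPT
  ))
  out
}

# batch SMILES -> titled canonical SMILES; NA where OpenBabel rejects the
# input. Titles are the element indices of `smiles`.
.ob_canonical <- function(smiles) {
  smiles <- as.character(smiles)
  res <- rep(NA_character_, length(smiles))
  # whitespace or empty strings never reach OpenBabel; SMILES proper cannot
  # contain blanks, which double as the title separator
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) & !grepl("[[:space:]]", smiles)
  if (!any(ok)) return(res)
  idx <- which(ok)
  inp <- paste(smiles[idx], idx, collapse = "\n")
  out <- .ob_convert("SMI", "CAN", inp)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smi <- vapply(parts, `[`, "", 1L)
    ttl <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    keep <- !is.na(ttl) & nzchar(smi)
    res[ttl[keep]] <- smi[keep]
  }
  res
}

#' Test whether strings are valid SMILES
#'
#' A string is valid when a molecular graph can be constructed from it.
#' Invalid input (unclosed rings, stray characters, empty strings) returns
#' `FALSE`; this function never raises.
#'
#' @param smiles Character vector.
#' @return Logical vector of the same length.
#' @export
#' @examples
#' is_valid_smiles(c("CCO", "C1CC", ""))
is_valid_smiles <- function(smiles) {
  if (length(smiles) == 0) return(logical(0))
  !is.na(.ob_canonical(smiles))
}

#' Canonicalize SMILES
#'
#' Returns the pinned canonical form (OpenBabel's canonical SMILES writer,
#' see [canonicalization_backend()]). Canonicalization is deterministic and
#' idempotent: all synonymous representations of a molecule collapse to one
#' string, and applying the function to its own output is the identity.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of canonical SMILES.
#' @export
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))  # identical output
canonicalize_smiles <- function(smiles) {
  res <- .ob_canonical(smiles)
  if (anyNA(res)) {
    bad <- smiles[which(is.na(res))[1]]
    abort(
      paste0("cannot parse SMILES: ", encodeString(bad, quote = "\"")),
      class = "tastekit_parse_error"
    )
  }
  res
}

#' Canonicalization backend metadata
#'
#' Identifies the toolkit and writer pinned as the package's canonical form,
#' recorded in configs and model archives for reproducibility.
#'
#' @return Named list with the backend name and version string.
#' @export
canonicalization_backend <- function() {
  list(
    backend = "openbabel/ChemmineOB",
    format = "can",
    chemmineob_version = as.character(utils::packageVersion("ChemmineOB"))
  )
}

# --- molblock plumbing -------------------------------------------------------

# batch SMILES -> V2000 molblocks, aligned with input; NA where invalid
.smiles_to_molblocks <- function(smiles) {
  smiles <- as.character(smiles)
  res <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles)) & !grepl("[[:space:]]", smiles)
  if (!any(ok)) return(res)
  idx <- which(ok)
  inp <- paste(smiles[idx], idx, collapse = "\n")
  out <- .ob_convert("SMI", "SDF", inp)
  if (!nzchar(out)) return(res)
  blocks <- strsplit(out, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  for (b in blocks) {
    first <- sub("\n.*$", "", b)
    ttl <- suppressWarnings(as.integer(trimws(first)))
    if (!is.na(ttl)) res[ttl] <- sub("^\n+", "", b)
  }
  res
}

# permute the atom order of a V2000 molblock; perm[i] = old index placed at
# position i
.permute_molblock <- function(lines, na, nb, perm) {
  pos <- integer(na)
  pos[perm] <- seq_len(na)
  atoms <- lines[5:(4 + na)]
  out <- lines
  out[5:(4 + na)] <- atoms[perm]
  if (nb > 0) {
    bonds <- lines[(5 + na):(4 + na + nb)]
    out[(5 + na):(4 + na + nb)] <- vapply(bonds, function(b) {
      a1 <- as.integer(substr(b, 1, 3))
      a2 <- as.integer(substr(b, 4, 6))
      paste0(
        formatC(pos[a1], width = 3), formatC(pos[a2], width = 3),
        substr(b, 7, nchar(b))
      )
    }, "", USE.NAMES = FALSE)
  }
  # renumber charge/property atom references
  chg <- grep("^M  (CHG|ISO|RAD)", out)
  for (i in chg) {
    f <- strsplit(trimws(out[i]), "[[:space:]]+")[[1]]
    nn <- as.integer(f[3])
    for (j in seq_len(nn)) {
      k <- 2 + 2 * j
      f[k] <- as.character(pos[as.integer(f[k])])
    }
    out[i] <- paste0(
      "M  ", f[2], formatC(nn, width = 3),
      paste0(vapply(seq_len(nn), function(j) {
        paste0(
          formatC(as.integer(f[2 + 2 * j]), width = 4),
          formatC(as.integer(f[3 + 2 * j]), width = 4)
        )
      }, ""), collapse = "")
    )
  }
  out
}

.molblock_counts <- function(lines) {
  c(
    na = as.integer(substr(lines[4], 1, 3)),
    nb = as.integer(substr(lines[4], 4, 6))
  )
}

#' Enumerate random synonymous SMILES
#'
#' Draws `k` alternative SMILES strings for one molecule by randomizing the
#' atom order before writing the string, the textual analogue of starting
#' the graph traversal at a random atom. Every returned string canonicalizes
#' back to `canonicalize_smiles(smiles)`; duplicates are permitted (small
#' molecules admit few distinct representations). Output is reproducible for
#' a fixed seed.
#'
#' @param smiles A single valid SMILES string.
#' @param k Number of variants to draw (>= 1).
#' @param seed Integer seed controlling the atom-order draws.
#' @return Character vector of length `k`.
#' @export
#' @examples
#' enumerate_smiles("CCO", k = 5, seed = 7)
enumerate_smiles <- function(smiles, k, seed = 1L) {
  stopifnot(length(smiles) == 1, k >= 1)
  out <- .augment_batch(smiles, k = as.integer(k), seed = as.integer(seed))
  out$variant_smiles
}

#' Molecular weight in Daltons
#'
#' Average molecular weight including implicit hydrogens, computed by the
#' cheminformatics backend.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Numeric vector of weights in Da.
#' @export
#' @examples
#' molecular_weight("CCO")  # ~46.07
molecular_weight <- function(smiles) {
  if (!length(smiles)) return(numeric(0))
  inp <- paste(smiles, seq_along(smiles), collapse = "\n")
  mw <- ChemmineOB::forEachMol("SMILES", inp, function(m) {
    ChemmineOB::prop_OB(m)$MW
  })
  unlist(mw)
}

# batch augmentation: k seeded variants for each input molecule with one
# OpenBabel round-trip. Returns tibble(parent, variant, variant_smiles).
.augment_batch <- function(smiles, k, seed = 1L) {
  smiles <- as.character(smiles)
  n <- length(smiles)
  blocks <- .smiles_to_molblocks(smiles)
  if (anyNA(blocks)) {
    bad <- smiles[which(is.na(blocks))[1]]
    abort(
      paste0("cannot parse SMILES: ", encodeString(bad, quote = "\"")),
      class = "tastekit_parse_error"
    )
  }
  pieces <- vector("list", n)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      lines <- strsplit(blocks[i], "\n", fixed = TRUE)[[1]]
      cnt <- .molblock_counts(lines)
      sub <- vector("list", k)
      for (j in seq_len(k)) {
        perm <- sample.int(cnt["na"])
        pl <- .permute_molblock(lines, cnt["na"], cnt["nb"], perm)
        pl[1] <- paste0(i, "_", j)  # title encodes parent and variant
        sub[[j]] <- paste(pl, collapse = "\n")
      }
      pieces[[i]] <- paste(unlist(sub), collapse = "\n$$$$\n")
    }
  })
  sdf <- paste0(paste(unlist(pieces), collapse = "\n$$$$\n"), "\n$$$$\n")
  out <- .ob_convert("SDF", "SMI", sdf)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[`, "", 1L)
  ttl <- vapply(parts, `[`, "", 2L)
  ij <- do.call(rbind, strsplit(ttl, "_", fixed = TRUE))
  res <- tibble(
    parent = as.integer(ij[, 1]),
    variant = as.integer(ij[, 2]),
    variant_smiles = smi
  )
  if (nrow(res) != n * k) {
    abort("SMILES enumeration lost molecules during conversion")
  }
  arrange(res, .data$parent, .data$variant)
}
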