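# Morgan (ECFP-style) fingerprints and the topological descriptor registry
# used by the tree-based backends. Fingerprints are computed on the
# molecular graph with order-invariant neighborhood hashing, so every
# SMILES form of a molecule yields identical bits.

# deterministic 31-bit string hash (polynomial rolling hash); doubles keep
# the intermediate products exact well below 2^53
.hash_str <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483629
  h
}

# per-atom Morgan invariants for radii 0..radius; returns the set of
# feature hashes of one molecule
.morgan_features <- function(graph, radius) {
  n <- graph$n_atoms
  inv <- vapply(seq_len(n), function(i) {
    .hash_str(paste(
      graph$elements[i], graph$degree[i], graph$implicit_h[i],
      graph$charge[i], as.integer(graph$in_ring[i]),
      sep = ","
    ))
  }, 0)
  feats <- inv
  nbrs <- lapply(seq_len(n), function(i) .neighbors(graph, i))
  for (r in seq_len(radius)) {
    inv_new <- vapply(seq_len(n), function(i) {
      nb <- nbrs[[i]]
      if (!length(nb$idx)) {
        pairs <- character(0)
      } else {
        pairs <- paste(nb$order, inv[nb$idx], sep = ":")
        pairs <- sort(pairs)
      }
      .hash_str(paste(r, inv[i], paste(pairs, collapse = "|"), sep = ";"))
    }, 0)
    inv <- inv_new
    feats <- c(feats, inv)
  }
  unique(feats)
}

#' Morgan fingerprint
#'
#' Hashed circular-substructure fingerprint (radius 2, 1024 bits by
#' default). Deterministic and invariant to the SMILES form: any synonymous
#' string of the same molecule produces the same bits.
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius Neighborhood radius (default 2).
#' @param n_bits Fingerprint length (default 1024).
#' @return Integer 0/1 matrix with `length(smiles)` rows and `n_bits`
#'   columns.
#' @export
#' @examples
#' fp <- morgan_fingerprint(c("CCO", "OCC"))
#' identical(fp[1, ], fp[2, ])
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 1024L) {
  # features are defined on the canonical molecular graph: canonicalizing
  # first removes any dependence on the input's atom order or kekulization
  graphs <- parse_molecules(canonicalize_smiles(smiles), strict = TRUE)
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(graphs)) {
    feats <- .morgan_features(graphs[[i]], radius)
    out[i, (feats %% n_bits) + 1L] <- 1L
  }
  out
}

#' Tanimoto similarity between two fingerprints
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in `[0, 1]` (1 for identical non-empty fingerprints).
#' @export
tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  inter / uni
}

# --- descriptor registry -----------------------------------------------------

.descriptor_registry <- function() {
  list(
    mol_weight = function(g, smiles) molecular_weight(smiles),
    heavy_atom_count = function(g, smiles) g$n_atoms,
    bond_count = function(g, smiles) nrow(g$bonds),
    ring_count = function(g, smiles) .ring_count(g),
    n_carbon = function(g, smiles) sum(g$elements == "C"),
    n_oxygen = function(g, smiles) sum(g$elements == "O"),
    n_nitrogen = function(g, smiles) sum(g$elements == "N"),
    n_sulfur = function(g, smiles) sum(g$elements == "S"),
    n_halogen = function(g, smiles) sum(g$elements %in% c("F", "Cl", "Br", "I")),
    h_bond_donors = function(g, smiles) {
      sum(g$elements %in% c("O", "N") & g$implicit_h >= 1)
    },
    h_bond_acceptors = function(g, smiles) sum(g$elements %in% c("O", "N")),
    n_double_bonds = function(g, smiles) sum(g$bonds[, "order"] == 2L),
    n_branch_points = function(g, smiles) sum(g$degree >= 3),
    wiener_index = function(g, smiles) {
      d <- igraph::distances(g$igraph)
      d[!is.finite(d)] <- 0  # disconnected fragments contribute nothing
      sum(d) / 2
    },
    hetero_fraction = function(g, smiles) {
      if (g$n_atoms == 0) 0 else sum(!g$elements %in% c("C", "H")) / g$n_atoms
    }
  )
}

#' Names of the default molecular descriptors
#'
#' Fifteen adjacency/topology-style descriptors. The set is a documented
#' default, not a fixed law: [descriptor_vector()] accepts any subset or
#' ordering, so the choice is configuration rather than code.
#'
#' @return Character vector of 15 descriptor names.
#' @export
taste_descriptor_names <- function() names(.descriptor_registry())

#' Molecular descriptor vector
#'
#' Computes named topological descriptors for each molecule in a fixed
#' order. Values are finite reals; a non-finite value is replaced by 0 with
#' a warning. Unknown descriptor names are an error.
#'
#' @param smiles Character vector of valid SMILES.
#' @param descriptors Character vector of descriptor names (default: the
#'   full 15-descriptor registry).
#' @return Numeric matrix, one row per molecule, one named column per
#'   descriptor.
#' @export
descriptor_vector <- function(smiles, descriptors = taste_descriptor_names()) {
  reg <- .descriptor_registry()
  unknown <- setdiff(descriptors, names(reg))
  if (length(unknown)) {
    abort(paste0("unknown descriptor(s): ", paste(unknown, collapse = ", ")),
          class = "tastekit_descriptor_error")
  }
  smiles <- canonicalize_smiles(smiles)  # form-invariant by construction
  graphs <- parse_molecules(smiles, strict = TRUE)
  out <- matrix(0, nrow = length(smiles), ncol = length(descriptors),
                dimnames = list(NULL, descriptors))
  for (i in seq_along(graphs)) {
    for (d in descriptors) {
      v <- reg[[d]](graphs[[i]], smiles[i])
      if (!is.finite(v)) {
        warn(paste0("non-finite value for descriptor ", d, "; replaced by 0"))
        v <- 0
      }
      out[i, d] <- v
    }
  }
  out
}

#' Feature matrix for tree-based backends
#'
#' Concatenates the Morgan fingerprint with the (optional) descriptor
#' block. Combined width is `n_bits + length(descriptors)`.
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius,n_bits Fingerprint parameters.
#' @param descriptors `NULL` for fingerprints only, `TRUE` for the default
#'   15-descriptor set, or a character vector of registry names.
#' @return Numeric matrix of features.
#' @export
featurize <- function(smiles, radius = 2L, n_bits = 1024L, descriptors = NULL) {
  fp <- morgan_fingerprint(smiles, radius = radius, n_bits = n_bits)
  colnames(fp) <- paste0("fp", seq_len(ncol(fp)))
  if (is.null(descriptors) || identical(descriptors, FALSE)) return(fp)
  if (isTRUE(descriptors)) descriptors <- taste_descriptor_names()
  desc <- descriptor_vector(smiles, descriptors)
  cbind(fp, desc)
}
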