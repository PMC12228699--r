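# Molecular graph parsing (via OpenBabel molblocks + ChemmineR) and the graph
# utilities built on it: implicit hydrogens, ring membership, fragment
# counts, and the substructure detectors used by the synthetic rule sets and
# the attribution tests.

# default valences for implicit-hydrogen assignment; elements not listed get
# no implicit hydrogens (metals, noble gases)
.DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Se = 2, As = 3
)

# parse molecules into graph records.
# Returns a list, one element per input SMILES:
#   list(n_atoms, elements, charge, bonds = matrix(a1, a2, order),
#        implicit_h, degree, in_ring, n_fragments)
# Invalid SMILES yield NULL entries when `strict = FALSE`, otherwise error.
parse_molecules <- function(smiles, strict = TRUE) {
  blocks <- .smiles_to_molblocks(smiles)
  if (strict && anyNA(blocks)) {
    bad <- smiles[which(is.na(blocks))[1]]
    abort(
      paste0("cannot parse SMILES: ", encodeString(bad, quote = "\"")),
      class = "tastekit_parse_error"
    )
  }
  ok <- which(!is.na(blocks))
  res <- vector("list", length(smiles))
  if (!length(ok)) return(res)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(paste0(blocks[ok], "\n$$$$"), tf, sep = "\n")
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  for (i in seq_along(ok)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    n_atoms <- nrow(ab)
    elements <- sub("_.*$", "", rownames(ab))
    if (!is.null(bb) && !is.matrix(bb)) bb <- matrix(bb, nrow = 1)
    bonds <- if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
      matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a1", "a2", "order")))
    } else {
      m <- cbind(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
      # OpenBabel writes kekulized blocks; treat residual aromatic order 4 as
      # single for valence purposes
      m[m[, "order"] == 4L, "order"] <- 1L
      m
    }
    charge <- integer(n_atoms)
    for (ln in grep("^M  CHG", strsplit(blocks[ok[i]], "\n")[[1]], value = TRUE)) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
      nn <- f[1]
      for (j in seq_len(nn)) charge[f[2 * j]] <- f[2 * j + 1]
    }
    res[[ok[i]]] <- .finish_graph(n_atoms, elements, charge, bonds)
  }
  res
}

.finish_graph <- function(n_atoms, elements, charge, bonds) {
  bondsum <- numeric(n_atoms)
  degree <- integer(n_atoms)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      a1 <- bonds[r, 1]; a2 <- bonds[r, 2]; o <- bonds[r, 3]
      bondsum[a1] <- bondsum[a1] + o
      bondsum[a2] <- bondsum[a2] + o
      degree[a1] <- degree[a1] + 1L
      degree[a2] <- degree[a2] + 1L
    }
  }
  dv <- unname(.DEFAULT_VALENCE[elements])
  dv[is.na(dv)] <- 0
  adj <- ifelse(dv > 0, charge, 0L)  # O- has valence 1, N+ has 4
  implicit_h <- pmax(0L, as.integer(dv + adj - bondsum))
  g <- igraph::make_empty_graph(n = n_atoms, directed = FALSE)
  if (nrow(bonds)) {
    g <- igraph::add_edges(g, t(bonds[, 1:2, drop = FALSE]))
  }
  comp <- igraph::components(g)
  in_ring <- rep(FALSE, n_atoms)
  if (nrow(bonds)) {
    bridges <- igraph::bridges(g)
    cyclic <- setdiff(seq_len(nrow(bonds)), as.integer(bridges))
    if (length(cyclic)) {
      in_ring[unique(as.vector(bonds[cyclic, 1:2]))] <- TRUE
    }
  }
  list(
    n_atoms = n_atoms, elements = elements, charge = charge, bonds = bonds,
    implicit_h = implicit_h, degree = degree, in_ring = in_ring,
    n_fragments = comp$no, igraph = g
  )
}

# neighbors of atom i as tibble-ish list(idx, order)
.neighbors <- function(graph, i) {
  b <- graph$bonds
  if (!nrow(b)) return(list(idx = integer(0), order = integer(0)))
  sel1 <- b[, 1] == i
  sel2 <- b[, 2] == i
  list(
    idx = c(b[sel2, 1], b[sel1, 2]),
    order = c(b[sel2, 3], b[sel1, 3])
  )
}

# cyclomatic ring count per molecule graph
.ring_count <- function(graph) {
  nrow(graph$bonds) - graph$n_atoms + graph$n_fragments
}

# --- substructure detectors --------------------------------------------------
# Each detector returns a list of integer vectors, one per match, giving the
# atom indices (1-based) of the matched group.

# carboxylic acid: C(=O)(O with implicit H); returns {C, =O, OH} triples
detect_carboxylic_acid <- function(graph) {
  out <- list()
  for (i in which(graph$elements == "C")) {
    nb <- .neighbors(graph, i)
    dbl_o <- nb$idx[graph$elements[nb$idx] == "O" & nb$order == 2]
    oh <- nb$idx[graph$elements[nb$idx] == "O" & nb$order == 1 &
                   graph$implicit_h[nb$idx] >= 1 & graph$charge[nb$idx] == 0 &
                   graph$degree[nb$idx] == 1]
    if (length(dbl_o) >= 1 && length(oh) >= 1) {
      out[[length(out) + 1L]] <- c(i, dbl_o[1], oh[1])
    }
  }
  out
}

# ester: C(=O)-O-C where the ether O has two heavy neighbors
detect_ester <- function(graph) {
  out <- list()
  for (i in which(graph$elements == "C")) {
    nb <- .neighbors(graph, i)
    dbl_o <- nb$idx[graph$elements[nb$idx] == "O" & nb$order == 2]
    eo <- nb$idx[graph$elements[nb$idx] == "O" & nb$order == 1 &
                   graph$degree[nb$idx] == 2]
    if (length(dbl_o) >= 1 && length(eo) >= 1) {
      out[[length(out) + 1L]] <- c(i, dbl_o[1], eo[1])
    }
  }
  out
}

# amide: C(=O)-N
detect_amide <- function(graph) {
  out <- list()
  for (i in which(graph$elements == "C")) {
    nb <- .neighbors(graph, i)
    dbl_o <- nb$idx[graph$elements[nb$idx] == "O" & nb$order == 2]
    nn <- nb$idx[graph$elements[nb$idx] == "N" & nb$order == 1]
    if (length(dbl_o) >= 1 && length(nn) >= 1) {
      out[[length(out) + 1L]] <- c(i, dbl_o[1], nn[1])
    }
  }
  out
}

# hydroxyl groups: O with one heavy neighbor (C), >=1 implicit H, neutral,
# excluding acid/ester oxygens (carbonyl-adjacent carbons)
detect_hydroxyl <- function(graph) {
  out <- list()
  for (i in which(graph$elements == "O")) {
    if (graph$degree[i] != 1 || graph$implicit_h[i] < 1 || graph$charge[i] != 0) next
    nb <- .neighbors(graph, i)
    if (nb$order[1] != 1) next
    cnb <- .neighbors(graph, nb$idx[1])
    carbonyl <- any(graph$elements[cnb$idx] == "O" & cnb$order == 2)
    if (!carbonyl) out[[length(out) + 1L]] <- c(nb$idx[1], i)
  }
  out
}

# molecule-level predicates used by rule sets
has_carboxylic_acid <- function(graph) length(detect_carboxylic_acid(graph)) > 0
has_amide <- function(graph) length(detect_amide(graph)) > 0
has_ester <- function(graph) length(detect_ester(graph)) > 0
n_hydroxyl <- function(graph) length(detect_hydroxyl(graph))
is_polycyclic <- function(graph) .ring_count(graph) >= 2
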