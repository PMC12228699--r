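# Seeded generators for rule-based synthetic tastant datasets (the
# structure -> label mapping is known exactly, enabling parameter-recovery
# and attribution tests) and for curation fixture files with planted
# defects in known counts.
#
# The rule set mirrors textbook structure--taste associations: carboxylic
# acids (the pKa 2-7 regime of water-soluble organic acids) taste sour;
# amides are a recurring motif of umami molecules; polyols and esters lean
# sweet; fused/linked polyaromatic (polyphenol-like) scaffolds lean bitter;
# everything else -- alkanes, simple ethers -- is undefined.

.DEFAULT_CLASS_MIX <- c(sweet = 0.61, bitter = 0.20, sour = 0.10,
                        umami = 0.01, undefined = 0.08)

#' Rule set mapping substructures to taste labels
#'
#' Ordered first-match-wins rules. At zero label noise the mapping is a
#' deterministic function of the molecular graph, which is what makes the
#' generated datasets usable as parameter-recovery ground truth.
#'
#' @param label_noise Probability in `[0, 0.5)` that a generated record's
#'   label is replaced by a uniformly random *other* label.
#' @param class_mix Named target class proportions (must cover the five
#'   labels, non-negative, summing to 1). The default emulates a strongly
#'   imbalanced tastant collection: sweet dominant, umami rare.
#' @return Object of class `taste_ruleset`.
#' @export
taste_ruleset <- function(label_noise = 0, class_mix = .DEFAULT_CLASS_MIX) {
  if (label_noise < 0 || label_noise >= 0.5) {
    abort("label_noise must lie in [0, 0.5)", class = "tastekit_ruleset_error")
  }
  if (!setequal(names(class_mix), taste_labels()) || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-6 || sum(class_mix > 0) == 0) {
    abort("class_mix must be named proportions over the five labels summing to 1",
          class = "tastekit_ruleset_error")
  }
  structure(list(
    rules = tibble(
      pattern = c("carboxylic_acid", "amide", "polyol_or_ester", "polycyclic"),
      label = c("sour", "umami", "sweet", "bitter")
    ),
    default_label = "undefined",
    label_noise = label_noise,
    class_mix = class_mix[taste_labels()]
  ), class = "taste_ruleset")
}

# first matching rule wins; hydroxyls on ring carbons do not count toward
# the polyol rule (they belong to the polyphenol motif)
.rule_label_one <- function(graph) {
  if (has_carboxylic_acid(graph)) return("sour")
  if (has_amide(graph)) return("umami")
  oh <- detect_hydroxyl(graph)
  aliphatic_oh <- sum(vapply(oh, function(m) !graph$in_ring[m[1]], NA))
  if (aliphatic_oh >= 2 || has_ester(graph)) return("sweet")
  if (is_polycyclic(graph)) return("bitter")
  "undefined"
}

#' Apply a rule set to molecules
#'
#' Returns the noiseless rule-based label for each molecule (first matching
#' rule wins; unmatched molecules get the default label).
#'
#' @param smiles Character vector of valid SMILES.
#' @param ruleset A [taste_ruleset()] (only the rules are used; noise is a
#'   generation-time property).
#' @return Factor of labels.
#' @export
apply_ruleset <- function(smiles, ruleset = taste_ruleset()) {
  graphs <- parse_molecules(smiles, strict = TRUE)
  taste_label(vapply(graphs, .rule_label_one, ""))
}

# --- molecule grammar --------------------------------------------------------
# scaffold + decoration composers; every emitted string is valid by
# construction and matches its intended rule

.gen_alkyl <- function(min_len = 2, max_len = 7) {
  len <- sample(min_len:max_len, 1)
  units <- vapply(seq_len(len), function(i) {
    if (i > 1 && i < len && runif(1) < 0.3) {
      if (runif(1) < 0.3) "C(CC)" else "C(C)"
    } else "C"
  }, "")
  paste(units, collapse = "")
}

.gen_sour <- function() {
  # carboxylic acid on an alkyl backbone; the acid group is the only
  # oxygen-bearing motif so the class marker is unambiguous
  paste0(.gen_alkyl(1, 8), "C(=O)O")
}

.gen_umami <- function() {
  # amide between two alkyl parts; no acid group
  a <- .gen_alkyl(1, 5)
  b <- .gen_alkyl(1, 4)
  if (runif(1) < 0.5) paste0(a, "C(=O)N", b) else paste0(a, "NC(=O)", b)
}

.gen_sweet <- function() {
  if (runif(1) < 0.5) {
    # polyol: >= 2 aliphatic hydroxyls
    len <- sample(3:7, 1)
    n_oh <- sample(2:min(4, len), 1)
    oh_at <- sort(sample(seq_len(len), n_oh))
    units <- vapply(seq_len(len), function(i) {
      if (i %in% oh_at) "C(O)" else "C"
    }, "")
    s <- paste(units, collapse = "")
    sub("C\\(O\\)$", "CO", s)  # terminal hydroxyl written plainly
  } else {
    # ester (no free acid): R-C(=O)-O-R'
    paste0(.gen_alkyl(1, 5), "C(=O)O", .gen_alkyl(1, 4))
  }
}

.BITTER_CORES <- c(
  "c1ccc(-c2ccccc2)cc1",
  "Oc1ccc(-c2ccccc2)cc1",
  "Oc1ccc(-c2ccc(O)cc2)cc1",
  "c1ccc2ccccc2c1",
  "Oc1ccc2ccccc2c1",
  "Oc1cccc2ccccc12",
  "c1ccc(-c2ccncc2)cc1",
  "Oc1ccc(-c2cccc(O)c2)cc1"
)

.gen_bitter <- function() {
  core <- sample(.BITTER_CORES, 1)
  tail_ <- sample(c("", "C", "CC", "CCC"), 1)
  paste0(tail_, core)
}

.gen_undefined <- function() {
  kind <- runif(1)
  if (kind < 0.45) {
    .gen_alkyl(4, 9)
  } else if (kind < 0.8) {
    paste0(.gen_alkyl(1, 4), "O", .gen_alkyl(1, 4))  # ether, no hydroxyl
  } else {
    paste0(.gen_alkyl(0 + 1, 3), "C1CCCCC1")  # single ring
  }
}

.CLASS_GENERATORS <- list(
  sweet = .gen_sweet, bitter = .gen_bitter, sour = .gen_sour,
  umami = .gen_umami, undefined = .gen_undefined
)

# largest-remainder apportionment of n over the class mix
.apportion <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

#' Generate a rule-based synthetic tastant dataset
#'
#' Molecules are assembled from a scaffold-plus-decoration grammar (alkyl
#' and aromatic scaffolds, functional-group decorations) so that every
#' record's noiseless label is reproduced exactly by [apply_ruleset()].
#' Class counts follow the rule set's `class_mix` by largest-remainder
#' apportionment; `label_noise` then relabels a random subset to a random
#' other class. Fully deterministic for a fixed seed.
#'
#' @param n Number of records (>= 1).
#' @param ruleset A [taste_ruleset()].
#' @param seed Integer seed.
#' @return Tibble with `smiles`, `label`, `rule_label` (the noiseless
#'   label) and `source = "synthetic"`.
#' @export
generate_taste_dataset <- function(n, ruleset = taste_ruleset(), seed = 1L) {
  stopifnot(n >= 1, inherits(ruleset, "taste_ruleset"))
  counts <- .apportion(n, ruleset$class_mix)
  withr::with_seed(seed, {
    smiles <- character(0)
    intended <- character(0)
    for (cls in names(counts)) {
      gen <- .CLASS_GENERATORS[[cls]]
      smiles <- c(smiles, vapply(seq_len(counts[[cls]]), function(i) gen(), ""))
      intended <- c(intended, rep(cls, counts[[cls]]))
    }
    ord <- sample(length(smiles))
    smiles <- smiles[ord]
    intended <- intended[ord]
    labels <- intended
    if (ruleset$label_noise > 0) {
      flip <- runif(length(labels)) < ruleset$label_noise
      labels[flip] <- vapply(labels[flip], function(l) {
        sample(setdiff(taste_labels(), l), 1)
      }, "")
    }
  })
  tibble(
    smiles = smiles,
    label = taste_label(labels),
    rule_label = taste_label(intended),
    source = "synthetic"
  )
}

#' Write a curation fixture file with planted defects
#'
#' Builds a CSV whose [curate()] report recovers the planted counts
#' exactly: `n_clean` well-formed unique records plus the requested numbers
#' of invalid strings, neutral multi-fragment entries, charged molecules,
#' over-2000-Da polymer-like chains, and duplicates (non-canonical rewrites
#' of clean rows with the same label, caught only after canonicalization).
#' Each defect is detected by exactly one filter stage.
#'
#' @param n_clean,n_invalid,n_multifragment,n_charged,n_overweight,n_duplicate
#'   Non-negative planted counts.
#' @param seed Integer seed.
#' @param path Output CSV path (default: a tempfile).
#' @return The path, invisibly; the planted counts are attached as
#'   attribute `"planted"`.
#' @export
make_curation_fixture <- function(n_clean = 20, n_invalid = 0,
                                  n_multifragment = 0, n_charged = 0,
                                  n_overweight = 0, n_duplicate = 0,
                                  seed = 1L, path = tempfile(fileext = ".csv")) {
  stopifnot(n_clean >= 0, n_invalid >= 0, n_multifragment >= 0,
            n_charged >= 0, n_overweight >= 0, n_duplicate >= 0)
  if (n_duplicate > 0 && n_clean == 0) {
    abort("duplicates require at least one clean row",
          class = "tastekit_fixture_error")
  }
  # clean block: canonically unique molecules labeled by the rule set
  clean <- tibble(smiles = character(0), label = character(0))
  if (n_clean > 0) {
    pool <- generate_taste_dataset(max(4 * n_clean, 40), seed = seed)
    canon <- canonicalize_smiles(pool$smiles)
    keep <- !duplicated(canon)
    pool <- pool[keep, ][seq_len(n_clean), ]
    clean <- tibble(smiles = pool$smiles, label = as.character(pool$rule_label))
  }
  rows <- list(clean)
  withr::with_seed(seed + 1L, {
    if (n_invalid > 0) {
      rows[[length(rows) + 1L]] <- tibble(
        smiles = vapply(seq_len(n_invalid), function(i) {
          paste0(strrep("C", 1 + i), "1")  # unmatched ring bond: never parses
        }, ""),
        label = sample(taste_labels(), n_invalid, replace = TRUE)
      )
    }
    if (n_multifragment > 0) {
      base <- unique(vapply(seq_len(n_multifragment * 3), function(i) {
        paste0(strrep("C", 3 + (i %% 5)), "C(C)", strrep("C", i %% 3))
      }, ""))[seq_len(n_multifragment)]
      rows[[length(rows) + 1L]] <- tibble(
        smiles = paste0(base, ".O"),  # tastant plus water, both neutral
        label = sample(taste_labels(), n_multifragment, replace = TRUE)
      )
    }
    if (n_charged > 0) {
      rows[[length(rows) + 1L]] <- tibble(
        smiles = vapply(seq_len(n_charged), function(i) {
          if (i %% 2 == 0) paste0(strrep("C", i), "C(=O)[O-]")
          else paste0(strrep("C", i), "C[NH3+]")
        }, ""),
        label = sample(taste_labels(), n_charged, replace = TRUE)
      )
    }
    if (n_overweight > 0) {
      rows[[length(rows) + 1L]] <- tibble(
        smiles = vapply(seq_len(n_overweight), function(i) {
          strrep("C", 145 + i)  # ~2040+ Da alkane chains
        }, ""),
        label = sample(taste_labels(), n_overweight, replace = TRUE)
      )
    }
    if (n_duplicate > 0) {
      src <- clean[rep(seq_len(nrow(clean)), length.out = n_duplicate), ]
      rewritten <- vapply(seq_len(nrow(src)), function(i) {
        vs <- enumerate_smiles(src$smiles[i], k = 6, seed = seed + i)
        alt <- vs[vs != src$smiles[i]]
        if (length(alt)) alt[1] else vs[1]
      }, "")
      rows[[length(rows) + 1L]] <- tibble(smiles = rewritten, label = src$label)
    }
    fixture <- bind_rows(rows)
    fixture <- fixture[sample(nrow(fixture)), ]
  })
  fixture$source <- "fixture"
  utils::write.csv(as.data.frame(fixture), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  attr(path, "planted") <- c(
    n_clean = n_clean, n_invalid = n_invalid,
    n_multifragment = n_multifragment, n_charged = n_charged,
    n_overweight = n_overweight, n_duplicate = n_duplicate
  )
  invisible(path)
}
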