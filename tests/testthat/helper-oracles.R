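# Independent oracles and shared fixtures for the test suite.

# ---- rooted-traversal SMILES oracle -----------------------------------------
# Brute-force enumeration of every SMILES string obtainable by a depth-first
# traversal of a small acyclic single-bonded molecule, starting from every
# atom and visiting children in every order. Independent of the package's
# SMILES writer; used to check that randomized enumeration reaches exactly
# the representations the graph admits.
oracle_rooted_smiles <- function(elements, edges) {
  n <- length(elements)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1]; b <- edges[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  write_from <- function(i, parent) {
    kids <- setdiff(adj[[i]], parent)
    if (!length(kids)) return(elements[i])
    out <- character(0)
    for (ord in perms(kids)) {
      sub <- lapply(ord, function(k) write_from(k, i))
      combos <- Reduce(function(acc, opts) {
        unlist(lapply(acc, function(a) paste0(a, "\r", opts)))
      }, sub[-1], init = sub[[1]])
      for (combo in combos) {
        parts <- strsplit(combo, "\r", fixed = TRUE)[[1]]
        nlast <- length(parts)
        branches <- if (nlast > 1) {
          paste0("(", parts[-nlast], ")", collapse = "")
        } else ""
        out <- c(out, paste0(elements[i], branches, parts[nlast]))
      }
    }
    out
  }
  unique(unlist(lapply(seq_len(n), function(i) write_from(i, 0L))))
}

# ---- per-sample counting oracle for the metric suite ------------------------
# Recomputes accuracy, per-class precision/recall/F1 and the macro/weighted
# averages by explicit loops over samples, independently of the package's
# confusion-matrix path.
oracle_metrics <- function(y_true, y_pred) {
  lv <- taste_labels()
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  per <- lapply(lv, function(cl) {
    tp <- 0; fp <- 0; fn <- 0; n <- 0
    for (i in seq_along(y_true)) {
      if (y_true[i] == cl) n <- n + 1
      if (y_pred[i] == cl && y_true[i] == cl) tp <- tp + 1
      if (y_pred[i] == cl && y_true[i] != cl) fp <- fp + 1
      if (y_pred[i] != cl && y_true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(n = n, precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  acc <- 0
  for (i in seq_along(y_true)) if (y_true[i] == y_pred[i]) acc <- acc + 1
  list(
    per_class = per,
    accuracy = acc / length(y_true),
    macro = colSums(per[, c("precision", "recall", "f1")]) / length(lv),
    weighted = colSums(per[, c("precision", "recall", "f1")] *
                         per[, "n"]) / sum(per[, "n"])
  )
}

# ---- cached fixtures --------------------------------------------------------
.tk_cache <- new.env(parent = emptyenv())

tk_cached <- function(name, build) {
  if (!exists(name, envir = .tk_cache)) {
    assign(name, build(), envir = .tk_cache)
  }
  get(name, envir = .tk_cache)
}

# token model trained on noisy synthetic data, with its held-out probe set
tk_noisy_token_fixture <- function() {
  tk_cached("noisy_token", function() {
    ds <- generate_taste_dataset(800, taste_ruleset(label_noise = 0.15),
                                 seed = 31)
    cur <- curate(ds)$records
    sp <- split_dataset(cur, 0.25, seed = 9)
    model <- taste_train(
      sp$train,
      taste_config("token_lm", learning_rate = 3e-3, epochs = 12, seed = 5)
    )
    list(model = model, split = sp)
  })
}

# token model trained on data whose only sour marker is the carboxylic acid
tk_acid_token_fixture <- function() {
  tk_cached("acid_token", function() {
    rs <- taste_ruleset(class_mix = c(sweet = 0.3, bitter = 0, sour = 0.4,
                                      umami = 0, undefined = 0.3))
    ds <- generate_taste_dataset(1200, rs, seed = 21)
    cur <- curate(ds)$records
    sp <- split_dataset(cur, 0.2, seed = 22)
    model <- taste_train(
      sp$train,
      taste_config("token_lm", learning_rate = 3e-3, epochs = 30, seed = 23)
    )
    list(model = model, split = sp)
  })
}

# small clean dataset + gbt model used by several evaluation tests
tk_clean_gbt_fixture <- function() {
  tk_cached("clean_gbt", function() {
    ds <- generate_taste_dataset(600, seed = 5)
    cur <- curate(ds)$records
    sp <- split_dataset(cur, 0.2, seed = 2)
    model <- taste_train(sp$train, taste_config("gbt", seed = 9))
    list(model = model, split = sp)
  })
}

# pool of strings with known defect kinds, for curation fuzzing
tk_defect_pool <- function() {
  tk_cached("defect_pool", function() {
    clean <- generate_taste_dataset(60, seed = 91)$smiles
    list(
      clean = unique(clean),
      invalid = paste0(strrep("C", 2:9), "1"),
      multifrag = paste0(unique(clean)[1:8], ".O"),
      charged = c("CC(=O)[O-]", "CCC(=O)[O-]", "CCCC[NH3+]", "[NH4+]",
                  "CC[N+](C)(C)C"),
      overweight = vapply(146:150, function(k) strrep("C", k), "")
    )
  })
}
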