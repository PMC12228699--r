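# Multi-class taste classifiers behind one train/predict surface.
# Backends: "gbt" (gradient-boosted trees, xgboost), "rf" (150-tree random
# forest), "balanced_rf" (random forest with per-class undersampling to the
# minority class size), and "token_lm" (a small token-level transformer
# trained with the fine-tuning recipe: cross-entropy, low learning rate,
# batch size 16, weight decay 0.01, best-checkpoint-by-eval-loss).

.BACKENDS <- c("gbt", "rf", "balanced_rf", "token_lm")

#' Training configuration
#'
#' Assembles and validates the training configuration shared by all
#' backends. Defaults follow the package's standard recipe: 150 trees for
#' the forests; for the token model a learning rate of 1e-5, batch size 16,
#' weight decay 0.01, and 20 epochs unaugmented or 2 epochs when a 10-fold
#' augmented dataset is used. `augmentation_fold = 0` disables training-time
#' SMILES augmentation; 10 is the standard augmented setting.
#'
#' @param backend One of `"gbt"`, `"rf"`, `"balanced_rf"`, `"token_lm"`.
#' @param n_trees Trees per forest / boosting rounds (default 150).
#' @param learning_rate Token-model learning rate (default 1e-5; training a
#'   small model from random initialization usually wants a larger value,
#'   e.g. 1e-2).
#' @param batch_size Token-model minibatch size (default 16).
#' @param weight_decay Decoupled weight decay (default 0.01).
#' @param epochs Training epochs; defaults to 20, or 2 when
#'   `augmentation_fold > 0`.
#' @param augmentation_fold k synonymous SMILES per training molecule
#'   (token model only; 0 = off). Expansion is uniform across classes --
#'   augmenting classes unevenly teaches the model the augmentation rate,
#'   not the chemistry.
#' @param seed Integer seed governing all randomness in training.
#' @param descriptors Passed to [featurize()] for tree backends.
#' @param max_depth,gbt_eta Gradient-boosting depth and shrinkage.
#' @param grid Optional named list (`max_depth`, `gbt_eta`) of candidate
#'   values for a small seeded grid search on a held-out slice (gbt only).
#' @param d_model,n_layers,d_ff Token-model dimensions (tiny transformer
#'   encoder: 2 layers by default).
#' @param eval_fraction Fraction of training rows held out for per-epoch
#'   evaluation loss and best-checkpoint selection.
#' @return Object of class `taste_config` (a validated list).
#' @export
taste_config <- function(backend = c("gbt", "rf", "balanced_rf", "token_lm"),
                         n_trees = 150L,
                         learning_rate = 1e-5,
                         batch_size = 16L,
                         weight_decay = 0.01,
                         epochs = NULL,
                         augmentation_fold = 0L,
                         seed = 1L,
                         descriptors = NULL,
                         max_depth = 6L,
                         gbt_eta = 0.3,
                         grid = NULL,
                         d_model = 32L,
                         n_layers = 2L,
                         d_ff = 64L,
                         eval_fraction = 0.1) {
  backend <- match.arg(backend)
  if (is.null(epochs)) epochs <- if (augmentation_fold > 0) 2L else 20L
  cfg <- list(
    backend = backend, n_trees = as.integer(n_trees),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    weight_decay = weight_decay, epochs = as.integer(epochs),
    augmentation_fold = as.integer(augmentation_fold), seed = as.integer(seed),
    descriptors = descriptors, max_depth = as.integer(max_depth),
    gbt_eta = gbt_eta, grid = grid, d_model = as.integer(d_model),
    n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
    eval_fraction = eval_fraction,
    canonicalization = canonicalization_backend()
  )
  stopifnot(
    cfg$n_trees >= 1, cfg$learning_rate > 0, cfg$batch_size >= 1,
    cfg$weight_decay >= 0, cfg$epochs >= 1, cfg$augmentation_fold >= 0,
    cfg$d_model >= 2, cfg$n_layers >= 1, cfg$d_ff >= 2,
    cfg$eval_fraction >= 0, cfg$eval_fraction < 1
  )
  structure(cfg, class = "taste_config")
}

.training_smiles <- function(records) {
  if ("canonical_smiles" %in% names(records)) records$canonical_smiles
  else records$smiles
}

#' Train a taste classifier
#'
#' Fits the backend named in `config` on a labeled training set. Tree
#' backends are trained on Morgan fingerprints (optionally concatenated
#' with descriptors); the token backend is trained on tokenized SMILES
#' strings with cross-entropy loss. When `config$augmentation_fold > 0`
#' (token backend), every training molecule is first expanded to that many
#' synonymous SMILES carrying the parent's label -- the expansion factor is
#' identical for every class.
#'
#' @param records Tibble with `smiles` (or `canonical_smiles`) and `label`.
#' @param config A [taste_config()].
#' @return Object of class `taste_model`.
#' @export
taste_train <- function(records, config = taste_config()) {
  stopifnot(inherits(config, "taste_config"))
  if (nrow(records) == 0) {
    abort("training set is empty", class = "tastekit_train_error")
  }
  y <- taste_label(as.character(records$label))
  if (length(unique(y)) < 2) {
    abort("training set must contain at least two classes",
          class = "tastekit_train_error")
  }
  smiles <- .training_smiles(records)
  if (config$backend == "token_lm") {
    if (config$augmentation_fold > 0) {
      aug <- .augment_batch(smiles, k = config$augmentation_fold,
                            seed = config$seed)
      smiles <- aug$variant_smiles
      y <- y[aug$parent]
    }
    fit <- .tlm_train(smiles, y, config)
    model <- list(backend = "token_lm", config = config, fit = fit,
                  label_levels = taste_labels())
  } else {
    x <- featurize(smiles, descriptors = config$descriptors)
    fit <- switch(config$backend,
      gbt = .fit_gbt(x, y, config),
      rf = .fit_rf(x, y, config, balanced = FALSE),
      balanced_rf = .fit_rf(x, y, config, balanced = TRUE)
    )
    model <- list(backend = config$backend, config = config, fit = fit,
                  label_levels = taste_labels(),
                  feature_spec = list(radius = 2L, n_bits = 1024L,
                                      descriptors = config$descriptors))
  }
  model$version <- as.character(utils::packageVersion("tastekit"))
  structure(model, class = "taste_model")
}

# --- gradient-boosted trees --------------------------------------------------

.fit_gbt <- function(x, y, config) {
  ylab <- as.integer(y) - 1L
  params_for <- function(depth, eta) {
    list(objective = "multi:softprob", num_class = 5L,
         max_depth = depth, eta = eta, nthread = 1L,
         seed = config$seed)
  }
  choose <- list(max_depth = config$max_depth, eta = config$gbt_eta)
  if (!is.null(config$grid)) {
    # seeded grid search on a held-out slice, scored by multiclass log-loss
    depths <- config$grid$max_depth %||% config$max_depth
    etas <- config$grid$gbt_eta %||% config$gbt_eta
    idx <- withr::with_seed(config$seed, sample(nrow(x)))
    n_val <- max(1L, floor(0.2 * nrow(x)))
    val <- idx[seq_len(n_val)]; trn <- idx[-seq_len(n_val)]
    dtrn <- xgboost::xgb.DMatrix(x[trn, , drop = FALSE], label = ylab[trn])
    dval <- xgboost::xgb.DMatrix(x[val, , drop = FALSE], label = ylab[val])
    best <- Inf
    for (d in depths) for (e in etas) {
      set.seed(config$seed)
      bst <- xgboost::xgb.train(params_for(d, e), dtrn,
                                nrounds = config$n_trees, verbose = 0)
      p <- predict(bst, dval)
      if (!is.matrix(p)) p <- matrix(p, ncol = 5, byrow = TRUE)
      ll <- -mean(log(pmax(p[cbind(seq_along(val), ylab[val] + 1L)], 1e-12)))
      if (ll < best) { best <- ll; choose <- list(max_depth = d, eta = e) }
    }
  }
  dall <- xgboost::xgb.DMatrix(x, label = ylab)
  set.seed(config$seed)
  bst <- xgboost::xgb.train(params_for(choose$max_depth, choose$eta), dall,
                            nrounds = config$n_trees, verbose = 0)
  list(booster_raw = xgboost::xgb.save.raw(bst), chosen = choose)
}

.gbt_booster <- function(fit) xgboost::xgb.load.raw(fit$booster_raw)

# --- random forests ----------------------------------------------------------

.fit_rf <- function(x, y, config, balanced) {
  yd <- droplevels(y)
  args <- list(x = x, y = yd, ntree = config$n_trees, keep.inbag = TRUE)
  if (balanced) {
    # undersample every class to the size of the rarest so each bootstrap
    # sees equal per-class counts
    m <- min(table(yd))
    args$strata <- yd
    args$sampsize <- rep(m, nlevels(yd))
    args$replace <- TRUE
  }
  fit <- withr::with_seed(config$seed, do.call(randomForest::randomForest, args))
  list(rf = fit, levels_present = levels(yd))
}

# --- prediction --------------------------------------------------------------

#' Predict class probabilities
#'
#' Returns the normalized probability distribution over the five taste
#' classes for each input SMILES. Tree backends are invariant to the SMILES
#' form (features are computed on the molecular graph); the token backend
#' reads the string as written, which is what the consensus confidence
#' metric exploits.
#'
#' @param model A `taste_model`.
#' @param smiles Character vector of valid SMILES.
#' @param .validate Check SMILES validity first (internal callers that
#'   already know their strings are valid may skip this).
#' @return Numeric matrix, one row per input, columns `taste_labels()`;
#'   rows sum to 1.
#' @export
predict_proba <- function(model, smiles, .validate = TRUE) {
  stopifnot(inherits(model, "taste_model"))
  if (.validate) {
    ok <- is_valid_smiles(smiles)
    if (!all(ok)) {
      abort(paste0("cannot parse SMILES: ",
                   encodeString(smiles[!ok][1], quote = "\"")),
            class = "tastekit_parse_error")
    }
  }
  p <- if (model$backend == "token_lm") {
    .tlm_predict_proba(model$fit, smiles)
  } else if (model$backend == "gbt") {
    x <- featurize(smiles, descriptors = model$config$descriptors)
    pr <- predict(.gbt_booster(model$fit), xgboost::xgb.DMatrix(x))
    if (is.matrix(pr)) pr else matrix(pr, ncol = 5, byrow = TRUE)
  } else {
    x <- featurize(smiles, descriptors = model$config$descriptors)
    pp <- predict(model$fit$rf, x, type = "prob")
    full <- matrix(0, nrow = nrow(pp), ncol = 5,
                   dimnames = list(NULL, taste_labels()))
    full[, colnames(pp)] <- pp
    full
  }
  colnames(p) <- taste_labels()
  sw <- rowSums(p)
  p / sw
}

#' Predict the taste label
#'
#' Argmax of [predict_proba()]; exact probability ties break toward the
#' lower label index (the fixed order sweet, bitter, sour, umami,
#' undefined).
#'
#' @inheritParams predict_proba
#' @return Factor of predicted labels with levels `taste_labels()`.
#' @export
predict_label <- function(model, smiles, .validate = TRUE) {
  p <- predict_proba(model, smiles, .validate = .validate)
  idx <- apply(p, 1, which.max)  # which.max takes the first maximum: low index
  factor(taste_labels()[idx], levels = taste_labels())
}

#' @export
print.taste_model <- function(x, ...) {
  cat("tastekit model\n")
  cat("  backend:", x$backend, "\n")
  cat("  seed:   ", x$config$seed, "\n")
  if (x$backend == "token_lm") {
    cat(sprintf("  transformer: %d layers, d_model %d, vocab %d\n",
                x$config$n_layers, x$config$d_model, length(x$fit$vocab)))
    cat(sprintf("  best eval loss: %.4f (epoch %d)\n",
                x$fit$best_eval_loss, x$fit$best_epoch))
  }
  invisible(x)
}

#' @rdname taste_train
#' @param x A `taste_model`.
#' @param ... Unused.
#' @export
glance.taste_model <- function(x, ...) {
  tibble(
    backend = x$backend,
    n_trees = if (x$backend %in% c("gbt", "rf", "balanced_rf")) x$config$n_trees else NA_integer_,
    epochs = if (x$backend == "token_lm") x$config$epochs else NA_integer_,
    augmentation_fold = x$config$augmentation_fold,
    seed = x$config$seed,
    best_eval_loss = if (x$backend == "token_lm") x$fit$best_eval_loss else NA_real_
  )
}

# --- serialization -----------------------------------------------------------

#' Save / load a trained model
#'
#' Writes a versioned archive (an RDS file holding the configuration and
#' the backend's parameter blob). The gradient-boosting backend is stored
#' through its raw serialization, so archives survive package upgrades of
#' the boosting library.
#'
#' @param model A `taste_model`.
#' @param path File path.
#' @return `save_taste_model`: `invisible(path)`; `load_taste_model`: the
#'   restored `taste_model`.
#' @export
save_taste_model <- function(model, path) {
  stopifnot(inherits(model, "taste_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_taste_model
#' @export
load_taste_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$backend) || !obj$backend %in% .BACKENDS) {
    abort("not a tastekit model archive", class = "tastekit_io_error")
  }
  structure(obj, class = "taste_model")
}
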