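test_that("probabilities are normalized and label order is fixed", {
  fx <- tk_clean_gbt_fixture()
  probe <- fx$split$test$canonical_smiles
  for (backend in c("gbt", "balanced_rf")) {
    m <- if (backend == "gbt") fx$model else {
      taste_train(fx$split$train, taste_config("balanced_rf", seed = 9))
    }
    p <- predict_proba(m, probe)
    expect_equal(dim(p), c(length(probe), 5))
    expect_identical(colnames(p), taste_labels())
    expect_true(all(p >= 0 & p <= 1))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
  }
})

test_that("gradient boosting separates a zero-noise rule-based set", {
  fx <- tk_clean_gbt_fixture()
  train_acc <- mean(
    predict_label(fx$model, fx$split$train$canonical_smiles) ==
      fx$split$train$label
  )
  expect_equal(train_acc, 1.0)
})

test_that("training is deterministic for a fixed config and seed", {
  fx <- tk_clean_gbt_fixture()
  m2 <- taste_train(fx$split$train, taste_config("gbt", seed = 9))
  probe <- fx$split$test$canonical_smiles[1:10]
  expect_identical(predict_proba(fx$model, probe), predict_proba(m2, probe))
})

test_that("balanced forests see equal per-class counts in every bootstrap", {
  ds <- generate_taste_dataset(400, seed = 61)
  cur <- curate(ds)$records
  m <- taste_train(cur, taste_config("balanced_rf", n_trees = 25, seed = 3))
  inbag <- m$fit$rf$inbag
  y <- droplevels(taste_label(as.character(cur$label)))
  per_tree_class_counts <- sapply(seq_len(ncol(inbag)), function(tree) {
    vapply(levels(y), function(l) sum(inbag[y == l, tree]), 0)
  })
  expect_true(all(per_tree_class_counts == min(table(y))))
})

test_that("invalid inputs and degenerate training sets raise typed errors", {
  fx <- tk_clean_gbt_fixture()
  expect_error(predict_proba(fx$model, "C1CC"), class = "tastekit_parse_error")
  expect_error(
    taste_train(tibble::tibble(smiles = character(0),
                               label = taste_label(character(0))),
                taste_config("gbt")),
    class = "tastekit_train_error"
  )
  one_class <- tibble::tibble(smiles = c("CCO", "CCC"),
                              label = taste_label(c("sweet", "sweet")))
  expect_error(taste_train(one_class, taste_config("gbt")),
               class = "tastekit_train_error")
})

test_that("training-time augmentation expands uniformly and preserves labels", {
  smis <- c("CCO", "CC(=O)O", "c1ccccc1O")
  aug <- tastekit:::.augment_batch(smis, k = 10, seed = 5)
  expect_equal(nrow(aug), 30)                       # n x k arithmetic
  expect_equal(as.vector(table(aug$parent)), rep(10, 3))  # uniform fold
  expect_identical(canonicalize_smiles(aug$variant_smiles),
                   canonicalize_smiles(smis)[aug$parent])
})

test_that("augmented training makes predictions robust to SMILES form", {
  ds <- generate_taste_dataset(600, seed = 51)
  cur <- curate(ds)$records
  sp <- split_dataset(cur, 0.25, seed = 2)
  m_un <- taste_train(sp$train, taste_config("token_lm", learning_rate = 3e-3,
                                             epochs = 12, seed = 4))
  m_aug <- taste_train(sp$train, taste_config("token_lm", learning_rate = 3e-3,
                                              epochs = 2,
                                              augmentation_fold = 5, seed = 4))
  expect_equal(m_aug$config$epochs, 2)  # augmented recipe default
  probe <- sp$test$canonical_smiles[1:50]
  flip_rate <- function(m) {
    total <- 0
    for (i in seq_along(probe)) {
      v <- enumerate_smiles(probe[i], 4, seed = 100 + i)
      pl <- predict_label(m, c(probe[i], v), .validate = FALSE)
      total <- total + mean(pl[-1] != pl[1])
    }
    total / length(probe)
  }
  fr_aug <- flip_rate(m_aug)
  fr_un <- flip_rate(m_un)
  expect_lte(fr_aug, 0.05)
  expect_gt(fr_un, fr_aug)
})

test_that("the token model learns: loss decreases and can saturate", {
  fx <- tk_noisy_token_fixture()
  hist <- fx$model$fit$history
  expect_lt(hist$train_loss[nrow(hist)], hist$train_loss[1])
  # overfit-two-samples sanity oracle: near-delta probabilities
  toy <- tibble::tibble(smiles = c("CCO", "CC(=O)O"),
                        label = taste_label(c("sweet", "sour")))
  m <- taste_train(toy, taste_config("token_lm", learning_rate = 5e-2,
                                     epochs = 60, eval_fraction = 0,
                                     seed = 8))
  p <- predict_proba(m, toy$smiles)
  expect_gt(p[1, "sweet"], 0.99)
  expect_gt(p[2, "sour"], 0.99)
})

test_that("exact probability ties break toward the lower label index", {
  # a zero-initialized token model scores every class identically
  fit <- list(
    vocab = c("<unk>", "C", "O"),
    params = tastekit:::.tlm_init_params(3, 8, 8, 1),
    pos = tastekit:::.tlm_positions(16, 8)
  )
  fit$params$Wc[] <- 0
  fit$params$bc[] <- 0
  m <- structure(list(backend = "token_lm", config = taste_config("token_lm"),
                      fit = fit, label_levels = taste_labels()),
                 class = "taste_model")
  p <- predict_proba(m, "CCO")
  expect_equal(max(p) - min(p), 0)
  expect_identical(as.character(predict_label(m, "CCO")), "sweet")
})

test_that("model archives round-trip through save/load", {
  fx <- tk_clean_gbt_fixture()
  path <- withr::local_tempfile(fileext = ".rds")
  save_taste_model(fx$model, path)
  back <- load_taste_model(path)
  expect_identical(predict_proba(back, "CCO"), predict_proba(fx$model, "CCO"))
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(load_taste_model(junk), class = "tastekit_io_error")
})
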