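lab <- function(x) factor(x, levels = taste_labels())

test_that("confusion matrices count true-by-predicted pairs", {
  y <- lab(c("sweet", "bitter", "sour"))
  cm_perfect <- taste_confusion(y, y)
  expect_true(all(cm_perfect[upper.tri(cm_perfect)] == 0))
  expect_true(all(cm_perfect[lower.tri(cm_perfect)] == 0))
  cm1 <- taste_confusion("sweet", "bitter")
  expect_equal(cm1["sweet", "bitter"], 1L)
  expect_equal(sum(cm1), 1L)
  withr::with_seed(5, {
    yt <- sample(taste_labels(), 200, replace = TRUE)
    yp <- sample(taste_labels(), 200, replace = TRUE)
    cm <- taste_confusion(yt, yp)
    expect_equal(rowSums(cm), table(lab(yt))[taste_labels()],
                 ignore_attr = TRUE)
  })
  expect_error(taste_confusion(c("sweet", "sour"), "sweet"),
               class = "tastekit_eval_error")
})

test_that("per-class metrics match hand counts, with the 0/0 convention", {
  cm <- diag(c(10, 10, 10, 10, 10))
  dimnames(cm) <- list(true = taste_labels(), predicted = taste_labels())
  pc <- per_class_metrics(cm)
  expect_true(all(pc$precision == 1 & pc$recall == 1 & pc$f1 == 1))

  # a 2x2 block embedded in the 5-class table: hand-counted oracle
  cm2 <- matrix(0L, 5, 5, dimnames = dimnames(cm))
  cm2[1, 1] <- 8L; cm2[1, 2] <- 2L; cm2[2, 1] <- 3L; cm2[2, 2] <- 7L
  pc2 <- per_class_metrics(cm2)
  expect_equal(pc2$precision[1], 8 / 11)
  expect_equal(pc2$recall[1], 8 / 10)
  # never-true, never-predicted class: 0 with a flag
  expect_equal(pc2$precision[5], 0)
  expect_equal(pc2$recall[5], 0)
  expect_true(pc2$flagged[5])
})

test_that("macro and weighted averages follow their definitions", {
  expect_equal(macro_average(c(1, 0.5, 0, 0.5, 1)), 0.6)
  expect_equal(macro_average(rep(0.37, 5)), 0.37)
  expect_equal(weighted_average(c(0.9, 0.5, 0, 0, 0), c(80, 20, 0, 0, 0)), 0.82)
  expect_equal(weighted_average(c(0.2, 0.4, 0.6, 0.8, 1), rep(7, 5)),
               macro_average(c(0.2, 0.4, 0.6, 0.8, 1)))
  expect_equal(weighted_average(c(0.3, 0, 0, 0, 0), c(5, 0, 0, 0, 0)), 0.3)
  expect_error(macro_average(numeric(0)), class = "tastekit_eval_error")
  expect_error(weighted_average(1, 0), class = "tastekit_eval_error")
  # brute-force mean agreement on random vectors
  withr::with_seed(8, {
    for (i in 1:100) {
      v <- runif(5)
      expect_equal(macro_average(v), sum(v) / 5, tolerance = 1e-12)
    }
  })
})

test_that("one-vs-rest AUROC is a rank statistic with midrank ties", {
  y <- lab(c(rep("sweet", 4), rep("bitter", 4)))
  p <- matrix(0.1, 8, 5)
  p[, 1] <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)  # perfect separation
  au <- ovr_auroc(y, p)
  expect_equal(au$auroc[1], 1.0)
  # reversing the scores flips the area
  p2 <- p; p2[, 1] <- rev(p[, 1])
  expect_equal(ovr_auroc(y, p2)$auroc[1], 0.0)
  # degenerate classes are flagged, not fatal
  expect_true(au$flagged[4])
  expect_true(is.na(au$auroc[4]))
  # cross-check against an established implementation
  withr::with_seed(9, {
    yt <- lab(sample(c("sweet", "bitter"), 60, replace = TRUE))
    score <- runif(60)
    pm <- matrix(0, 60, 5); pm[, 1] <- score
    ours <- ovr_auroc(yt, pm)$auroc[1]
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = yt == "sweet", predictor = score, quiet = TRUE,
      direction = "<"
    )))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("binary reduction dominates multi-class accuracy and matches hand counts", {
  withr::with_seed(10, {
    for (i in 1:200) {
      n <- sample(5:60, 1)
      yt <- sample(taste_labels(), n, replace = TRUE)
      yp <- sample(taste_labels(), n, replace = TRUE)
      pos <- sample(taste_labels(), 1)
      b <- binary_reduction(yt, yp, pos)
      expect_gte(b$accuracy, mean(yt == yp))
    }
  })
  # hand-counted example
  yt <- c("sweet", "sweet", "bitter", "sour", "umami")
  yp <- c("sweet", "bitter", "sweet", "sour", "umami")
  b <- binary_reduction(yt, yp, "sweet")
  expect_equal(b$accuracy, 3 / 5)
  expect_equal(b$precision, 1 / 2)
  expect_equal(b$recall, 1 / 2)
  expect_equal(b$f1, 1 / 2)
  # all-positive degenerate case
  b2 <- binary_reduction(rep("sweet", 4), rep("sweet", 4), "sweet")
  expect_equal(b2$accuracy, 1)
  expect_equal(b2$f1, 1)
  # abstentions are excluded and reported as support
  b3 <- binary_reduction(yt, c(yp[1:4], NA), "sweet")
  expect_equal(b3$support, 4 / 5)
  expect_equal(b3$n, 4L)
})

test_that("the multi-label threshold rule categorizes molecules exclusively", {
  p <- rbind(
    c(0.5, 0.3, 0.1, 0.05, 0.05),   # exact {sweet, bitter}
    c(0.2, 0.2, 0.2, 0.2, 0.2),     # strict > leaves the set empty
    c(0.9, 0.04, 0.02, 0.02, 0.02), # collapsed onto sweet (correct)
    c(0.4, 0.3, 0.25, 0.03, 0.02)   # superset: too many
  )
  truth <- list(c("sweet", "bitter"), c("sweet", "bitter"),
                c("sweet", "bitter"), c("sweet", "bitter"))
  out <- multilabel_eval(p, truth)
  expect_equal(out$n_total, 4)
  expect_equal(out$n_exact, 1)
  expect_equal(out$n_too_many, 1)
  expect_equal(out$n_collapsed, 1)
  expect_equal(out$n_collapsed_correct, 1)
  expect_identical(out$detail$category,
                   c("exact", "other", "collapsed", "too_many"))
})

test_that("evaluate_model agrees with the per-sample counting oracle", {
  fx <- tk_clean_gbt_fixture()
  ev <- evaluate_model(fx$model, fx$split$test)
  yp <- predict_label(fx$model, fx$split$test$canonical_smiles)
  orc <- oracle_metrics(fx$split$test$label, yp)
  expect_equal(ev$accuracy, orc$accuracy, tolerance = 1e-12)
  expect_equal(ev$macro$f1, unname(orc$macro["f1"]), tolerance = 1e-12)
  expect_equal(ev$weighted$precision, unname(orc$weighted["precision"]),
               tolerance = 1e-12)
  expect_equal(ev$support_fraction, 1.0)
  # a zero-abstain consensus gives identical headline metrics
  ev_conf <- evaluate_model(fx$model, fx$split$test,
                            confidence = list(k = 6, threshold = 6, seed = 2))
  expect_equal(ev_conf$accuracy, ev$accuracy)
  expect_equal(ev_conf$support_fraction, 1.0)
  expect_error(evaluate_model(fx$model, fx$split$test[0, ]),
               class = "tastekit_eval_error")
})
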