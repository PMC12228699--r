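test_that("integrated gradients recover closed forms", {
  w <- c(2, -1, 0.5, 3)
  x <- c(1, 3, -2, 0.25)
  f_lin <- function(z) sum(w * z)
  g_lin <- function(z) w
  # linear scorer, zero baseline: attribution is w_i * x_i at any step count
  for (steps in c(2, 16, 64)) {
    a <- integrated_gradients(f_lin, x, n_steps = steps, grad_fn = g_lin)
    expect_equal(a, w * x, tolerance = 1e-12)
  }
  # x at the baseline: zero everywhere
  a0 <- integrated_gradients(f_lin, x, baseline = x, grad_fn = g_lin)
  expect_equal(a0, rep(0, 4))
  # quadratic scorer: analytic path integral gives (2-0) * int 2*(2a) da = 4
  aq <- integrated_gradients(function(z) sum(z^2), 2, baseline = 0,
                             n_steps = 64, grad_fn = function(z) 2 * z)
  expect_equal(aq, 4, tolerance = 1e-3)
  # numerical fallback agrees with the analytic gradient path
  afd <- integrated_gradients(f_lin, x, n_steps = 8)
  expect_equal(afd, w * x, tolerance = 1e-6)
})

test_that("shape and step-count preconditions are enforced", {
  f <- function(z) sum(z)
  expect_error(integrated_gradients(f, c(1, 2), baseline = c(0, 0, 0)),
               class = "tastekit_attribution_error")
  expect_error(integrated_gradients(f, c(1, 2), n_steps = 1),
               class = "tastekit_attribution_error")
  expect_error(
    integrated_gradients(f, 1, grad_fn = function(z) NaN),
    class = "tastekit_attribution_error"
  )
})

test_that("the sensitivity axiom holds for constructed linear scorers", {
  withr::with_seed(12, {
    for (rep_i in 1:10) {
      w <- rnorm(6)
      x1 <- rnorm(6)
      i <- sample(6, 1)
      x2 <- x1; x2[i] <- x2[i] + 1  # differ only in feature i
      f <- function(z) sum(w * z)
      a <- integrated_gradients(f, x2, baseline = x1,
                                grad_fn = function(z) w)
      if (f(x2) != f(x1)) expect_true(a[i] != 0)
      expect_equal(sum(a), f(x2) - f(x1), tolerance = 1e-10)
    }
  })
})

test_that("the completeness gap shrinks as the path is refined", {
  # the midpoint-rule error decays like 1/n^2 asymptotically but its sign
  # oscillates at coarse step counts, so individual doublings need not
  # shrink the gap; what refinement guarantees is the trend across decades
  # of step counts, and completeness at the default resolution
  fx <- tk_noisy_token_fixture()
  ratios <- numeric(0)
  for (j in c(3, 5, 8)) {
    s <- fx$split$test$canonical_smiles[j]
    gaps <- vapply(c(2, 128), function(ns) {
      a <- atom_attributions(fx$model, s, "sweet", n_steps = ns)
      abs(a$total_attribution - a$score_delta)
    }, 0)
    expect_lte(gaps[2], gaps[1])
    ratios <- c(ratios, gaps[2] / gaps[1])
    # at the default step count the gap is far below 2% of the score change
    a64 <- atom_attributions(fx$model, s, "sweet", n_steps = 64)
    expect_lt(abs(a64$total_attribution - a64$score_delta),
              0.02 * max(abs(a64$score_delta), 1e-8))
  }
  expect_lt(stats::median(ratios), 0.1)  # ~n^-2 decay over two decades
})

test_that("atom mapping, residual mass, and head-negation symmetry hold", {
  fx <- tk_noisy_token_fixture()
  m <- fx$model
  a <- atom_attributions(m, "c1ccccc1O", "bitter")
  expect_length(a$atom_scores, 7)  # six ring atoms + hydroxyl oxygen
  expect_equal(sum(a$atom_scores) + a$residual_nonatom, a$total_attribution,
               tolerance = 1e-12)
  # negating the target class column of the head negates all attributions
  m_neg <- m
  m_neg$fit$params$Wc[, 2] <- -m_neg$fit$params$Wc[, 2]
  m_neg$fit$params$bc[2] <- -m_neg$fit$params$bc[2]
  a_neg <- atom_attributions(m_neg, "c1ccccc1O", "bitter")
  expect_equal(a_neg$atom_scores, -a$atom_scores, tolerance = 1e-10)
})

test_that("a planted acid-to-sour rule concentrates attribution on the acid group", {
  fx <- tk_acid_token_fixture()
  acids <- fx$split$test$canonical_smiles[fx$split$test$rule_label == "sour"]
  acids <- head(acids, 15)
  hits <- 0
  for (s in acids) {
    a <- atom_attributions(fx$model, s, "sour")
    g <- tastekit:::parse_molecules(s)[[1]]
    cooh <- unique(unlist(tastekit:::detect_carboxylic_acid(g)))
    if (which.max(a$atom_scores) %in% cooh) hits <- hits + 1
  }
  expect_gte(hits / length(acids), 0.8)
})

test_that("tree backends are rejected and exports round-trip", {
  fx <- tk_clean_gbt_fixture()
  expect_error(atom_attributions(fx$model, "CCO", "sweet"),
               class = "tastekit_unsupported_backend")
  tk <- tk_noisy_token_fixture()
  a <- atom_attributions(tk$model, "CC(=O)O", "sour")
  path <- withr::local_tempfile(fileext = ".json")
  export_heatmap(a, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$atom_scores, a$atom_scores, tolerance = 1e-12)
  expect_identical(order(back$atom_scores), order(a$atom_scores))
  expect_equal(back$residual_nonatom, a$residual_nonatom, tolerance = 1e-12)
})
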