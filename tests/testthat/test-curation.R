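recs <- function(smiles, label = "sweet") {
  tibble::tibble(smiles = smiles, label = taste_label(rep(label, length(smiles))))
}

test_that("the validity filter removes exactly the unparseable rows", {
  r <- filter_invalid(recs(c("CCO", "C1CC")))
  expect_identical(r$kept$smiles, "CCO")
  expect_equal(nrow(r$removed), 1)
  expect_equal(nrow(filter_invalid(recs(c("CCO", "CC")))$removed), 0)
  expect_equal(nrow(filter_invalid(recs(c("C1CC", "CC1")))$kept), 0)
})

test_that("the fragment filter removes neutral multi-fragment entries only", {
  r <- filter_multifragment(recs(c("CCO.O", "CCO", "[Na+].[Cl-]")))
  # solvent-containing ethanol+water goes; the charged salt pair is left to
  # the charge filter
  expect_identical(r$removed$smiles, "CCO.O")
  expect_setequal(r$kept$smiles, c("CCO", "[Na+].[Cl-]"))
})

test_that("the charge filter removes any formally charged species", {
  r <- filter_charged(recs(c("[Na+].[Cl-]", "CC(=O)[O-]", "CC(=O)O")))
  expect_setequal(r$removed$smiles, c("[Na+].[Cl-]", "CC(=O)[O-]"))
  expect_identical(r$kept$smiles, "CC(=O)O")
})

test_that("the weight filter keeps strictly-below-cutoff molecules", {
  heavy <- strrep("C", 150)  # ~2100 Da alkane
  glucose <- "OCC1OC(O)C(O)C(O)C1O"
  r <- filter_weight(recs(c(heavy, glucose)))
  expect_identical(r$removed$smiles, heavy)
  expect_identical(r$kept$smiles, glucose)
  # boundary: a molecule at exactly the cutoff is removed
  r2 <- filter_weight(recs("CCO"), max_da = molecular_weight("CCO"))
  expect_equal(nrow(r2$kept), 0)
})

test_that("deduplication collapses same-label rows but keeps multi-taste rows", {
  r <- standardize_records(recs(c("CCO", "OCC")))
  d <- deduplicate_records(r)
  expect_equal(nrow(d$kept), 1)
  expect_equal(d$removed_count, 1)

  multi <- standardize_records(tibble::tibble(
    smiles = c("CCO", "OCC"),
    label = taste_label(c("sweet", "bitter"))
  ))
  d2 <- deduplicate_records(multi)
  expect_equal(nrow(d2$kept), 2)  # bittersweet convention: one row per taste
  expect_equal(d2$removed_count, 0)

  empty <- deduplicate_records(standardize_records(recs(character(0))))
  expect_equal(nrow(empty$kept), 0)
  expect_equal(empty$removed_count, 0)
})

test_that("curate attributes each removed row to exactly one stage", {
  path <- make_curation_fixture(20, 5, 4, 3, 2, 6, seed = 11)
  cur <- curate(read_taste_csv(path))
  rep_ <- cur$report
  expect_equal(rep_$n_input, 40)
  expect_equal(rep_$removed_invalid, 5)
  expect_equal(rep_$removed_multifragment, 4)
  expect_equal(rep_$removed_charged, 3)
  expect_equal(rep_$removed_overweight, 2)
  expect_equal(rep_$removed_duplicate, 6)
  expect_equal(rep_$n_output, 20)
  # an invalid multi-fragment-looking string counts only as invalid
  odd <- curate(recs(c("CCO.O1", "CCO")))
  expect_equal(odd$report$removed_invalid, 1)
  expect_equal(odd$report$removed_multifragment, 0)
  # clean input removes nothing
  clean <- curate(recs(c("CCO", "CCC")))
  expect_equal(clean$report$n_output, 2)
  expect_equal(clean$report$n_input - clean$report$n_output, 0)
})

test_that("curation is idempotent and conserves counts", {
  pool <- tk_defect_pool()
  withr::with_seed(7, {
    for (rep_i in 1:10) {
      smi <- c(
        sample(pool$clean, sample(3:10, 1)),
        sample(pool$invalid, sample(0:3, 1)),
        sample(pool$multifrag, sample(0:3, 1)),
        sample(pool$charged, sample(0:3, 1)),
        sample(pool$overweight, sample(0:2, 1))
      )
      r <- recs(sample(smi))
      cur <- curate(r)
      s <- cur$report
      expect_equal(
        s$n_input,
        s$n_output + s$removed_invalid + s$removed_multifragment +
          s$removed_charged + s$removed_overweight + s$removed_duplicate
      )
      second <- curate(cur$records)
      expect_equal(second$report$n_input, second$report$n_output)
    }
  })
})

test_that("label corrections are applied before deduplication", {
  r <- recs(c("CCO", "OCC"))
  fix <- tibble::tibble(canonical_smiles = canonicalize_smiles("CCO"),
                        label = "bitter")
  cur <- curate(r, corrections = fix)
  expect_equal(nrow(cur$records), 1)  # both rows corrected, then deduplicated
  expect_identical(as.character(cur$records$label), "bitter")
})

test_that("splits are grouped by molecule, sized, and leak-free", {
  ds <- generate_taste_dataset(300, seed = 13)
  cur <- curate(ds)$records
  # add multi-label duplicates to exercise co-partitioning
  extra <- cur[1:10, ]
  extra$label <- taste_label(rep("undefined", 10))
  full <- dplyr::bind_rows(cur, extra)

  sp <- split_dataset(full, 0.15, seed = 3)
  expect_length(intersect(sp$train$canonical_smiles, sp$test$canonical_smiles), 0)
  n_mols <- length(unique(full$canonical_smiles))
  expect_equal(length(unique(sp$test$canonical_smiles)), round(0.15 * n_mols))
  # multi-label rows co-partitioned
  for (cs in unique(extra$canonical_smiles)) {
    expect_false(cs %in% sp$train$canonical_smiles &&
                   cs %in% sp$test$canonical_smiles)
  }
  # determinism
  sp2 <- split_dataset(full, 0.15, seed = 3)
  expect_identical(sp$test$canonical_smiles, sp2$test$canonical_smiles)
  expect_error(split_dataset(full, 1.5, seed = 1),
               class = "tastekit_split_error")
})
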