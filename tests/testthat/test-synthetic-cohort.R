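test_that("degenerate all-genetic truth gives MZ cross-twin correlation near 1", {
  tr <- truth_record(te_mix = c(0.999, 1e-6, 1e-4, 1e-6))
  g <- generate_cohort(plain_spec(n_mz = 1000, n_dz = 0, seed = 7), tr)
  lia <- g$cohort$te_liability
  r <- cor(lia[c(TRUE, FALSE)], lia[c(FALSE, TRUE)])
  expect_gt(r, 0.99)
})

test_that("null paths give near-zero exposure-outcome correlation", {
  tr <- small_truth(a = 0, b = 0, c = 0)
  g <- generate_cohort(plain_spec(n_mz = 0, n_dz = 0, n_sing = 8000, seed = 3),
                       tr)
  r <- cor(g$cohort$te_liability, g$cohort$ptsdsx_liability)
  expect_lt(abs(r), 3 / sqrt(8000) * 3)
})

test_that("DZ cross-twin covariance matches the 0.5 VA + VC closed form", {
  tr <- truth_record(te_mix = c(0.5, 0.3, 0.2, 0))
  g <- generate_cohort(plain_spec(n_mz = 0, n_dz = 5000, seed = 11), tr)
  cv <- cross_twin_cov(g$cohort$te_liability, g$cohort$relation, "DZ")
  # 3 Monte-Carlo SEs of a covariance of correlated unit-variance pairs
  se <- sqrt((1 + 0.55^2) / 5000)
  expect_lt(abs(cv - 0.55), 3 * se)
})

test_that("MZ minus DZ cross-twin covariance recovers half the additive variance", {
  for (mix in list(c(0.6, 0.2, 0.2, 0), c(0.3, 0.4, 0.3, 0))) {
    tr <- truth_record(te_mix = mix)
    g <- generate_cohort(plain_spec(n_mz = 4000, n_dz = 4000, seed = 13), tr)
    dmz <- cross_twin_cov(g$cohort$te_liability, g$cohort$relation, "MZ")
    ddz <- cross_twin_cov(g$cohort$te_liability, g$cohort$relation, "DZ")
    se <- sqrt(2 * (1 + 1) / 4000)
    expect_lt(abs((dmz - ddz) - 0.5 * mix[1] / sum(mix)), 3 * se)
  }
})

test_that("standardized phenotypes have unit empirical variance", {
  tr <- small_truth()
  g <- generate_cohort(plain_spec(n_mz = 1500, n_dz = 1500, n_sing = 2000,
                                  seed = 17), tr)
  for (col in c("te_liability", "ptsdsx_liability", "roi_1"))
    expect_lt(abs(var(g$cohort[[col]]) - 1), 0.08)
})

test_that("the same seed regenerates a bit-identical cohort", {
  tr <- small_truth()
  sp <- cohort_spec(n_mz_pairs = 50, n_dz_pairs = 50, n_singletons = 50,
                    seed = 23)
  g1 <- generate_cohort(sp, tr)
  g2 <- generate_cohort(sp, tr)
  expect_identical(g1$cohort, g2$cohort)
})

test_that("invalid spec fields are rejected with the field named", {
  expect_error(cohort_spec(n_mz_pairs = -1), "n_mz_pairs")
  expect_error(cohort_spec(n_mz_pairs = 0, n_dz_pairs = 0, n_sib_pairs = 0,
                           n_singletons = 0), "family type")
  expect_error(cohort_spec(qc_fail_rate = 1.5), "qc_fail_rate")
  expect_error(truth_record(mediators = "m", a = 1.2, b = 0), "a")
  expect_error(truth_record(te_mix = c(0.5, 0.5, 0, 0)), "te_mix")
})

test_that("item responses follow the 2PL curve at its anchor points", {
  ip <- data.frame(discrimination = c(1.5, 2), difficulty = c(0.5, 2))
  # theta at the difficulty: endorsement ~ 50%
  set.seed(1)
  y <- generate_item_responses(rep(0.5, 20000), ip[1, ])
  expect_lt(abs(mean(y) - 0.5), 0.02)
  # huge discrimination, theta below difficulty: endorsement -> 0
  steep <- data.frame(discrimination = 60, difficulty = 1)
  y0 <- generate_item_responses(rep(0.5, 2000), steep)
  expect_lt(mean(y0), 0.005)
  expect_error(generate_item_responses(0, data.frame(discrimination = -1,
                                                     difficulty = 0)),
               "positive")
})

test_that("zero-endorsement calibration hits the configured target", {
  tr <- truth_record()
  sp <- cohort_spec(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 8000,
                    zero_te_target = 0.6195, qc_fail_rate = 0,
                    outlier_rate = 0, seed = 31)
  g <- generate_cohort(sp, tr)
  te <- g$cohort[grep("^te_item_", names(g$cohort))]
  p0 <- mean(rowSums(te) == 0)
  expect_lt(abs(p0 - 0.6195), 0.02)
})

test_that("QC failures and outliers occur at the configured rates", {
  tr <- small_truth()
  sp <- cohort_spec(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 10000,
                    zero_te_target = NULL, qc_fail_rate = 0.068,
                    outlier_rate = 0, seed = 37)
  g <- generate_cohort(sp, tr)
  n_fail <- sum(g$cohort$qc_score < 600)
  expect_lt(abs(n_fail - 680), 3 * sqrt(10000 * 0.068 * 0.932))

  sp0 <- cohort_spec(n_mz_pairs = 0, n_dz_pairs = 0, n_singletons = 2000,
                     zero_te_target = NULL, qc_fail_rate = 0,
                     outlier_rate = 0, seed = 41)
  g0 <- generate_cohort(sp0, tr)
  expect_equal(sum(g0$cohort$qc_score < 600), 0)

  # outlier_rate = 0 leaves ROI values untouched apart from the qc column
  set.seed(5)
  tab <- g0$cohort
  tab2 <- inject_missingness_and_outliers(tab, sp0, roi_cols = "roi_1")
  expect_identical(tab2$roi_1, tab$roi_1)
})

test_that("Monte-Carlo implied covariance matches the closed forms", {
  tr <- truth_record(te_mix = c(0.5, 0.3, 0.2, 0))
  mc <- monte_carlo_implied_cov(tr, "MZ", 100000)
  expect_lt(abs(mc["te_1", "te_2"] - 0.8), 3 * sqrt(2 / 100000) * 3)
  trs <- truth_record(te_mix = c(0.4, 0.3, 0.2, 0.1))
  mcu <- monte_carlo_implied_cov(trs, "unrelated_same_site", 100000)
  expect_lt(abs(mcu["te_1", "te_2"] - 0.1), 0.02)
  tre <- truth_record(te_mix = c(1e-6, 1e-6, 0.999, 1e-6))
  mce <- monte_carlo_implied_cov(tre, "DZ", 50000)
  expect_lt(abs(mce["te_1", "te_2"]), 0.02)
  expect_error(monte_carlo_implied_cov(tr, "COUSIN"), "pair")
  expect_error(monte_carlo_implied_cov(tr, "MZ", 10), "n_replicates")
})

test_that("cohorts round-trip through CSV with their metadata sidecar", {
  tr <- small_truth()
  sp <- plain_spec(n_mz = 20, n_dz = 20, seed = 43)
  g <- generate_cohort(sp, tr)
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort(g$cohort, path, truth = g$truth, spec = sp)
  back <- read_cohort(path)
  expect_equal(nrow(back), nrow(g$cohort))
  expect_equal(back$te_liability, g$cohort$te_liability, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$spec$seed, 43)
  expect_equal(meta$truth$paths$c, 0.5)
})
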