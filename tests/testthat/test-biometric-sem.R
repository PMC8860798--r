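test_that("implied pair covariances match the biometric closed forms", {
  vc <- list(te = variance_components(0.5, 0.3, 0.2, 0))
  mod <- variance_model("te")
  prm <- list(paths = numeric(0), components = vc)
  mz <- build_implied_cov(mod, prm, "MZ")
  expect_equal(unname(mz$cov), matrix(c(1, 0.8, 0.8, 1), 2), tolerance = 1e-12)
  dz <- build_implied_cov(mod, prm, "DZ")
  expect_equal(dz$cov[1, 2], 0.55, tolerance = 1e-12)
  vcs <- list(te = variance_components(0.4, 0.3, 0.2, 0.1))
  un <- build_implied_cov(mod, list(paths = numeric(0), components = vcs),
                          "unrelated_same_site")
  expect_equal(un$cov[1, 2], 0.1, tolerance = 1e-12)
  # site-sharing also contributes exactly var_S in the twin covariances
  mzs <- build_implied_cov(mod, list(paths = numeric(0), components = vcs), "MZ")
  expect_equal(mzs$cov[1, 2], 0.4 + 0.3 + 0.1, tolerance = 1e-12)
})

test_that("trivariate implied covariance agrees with the Monte-Carlo oracle", {
  tr <- small_truth(a = 0.15, b = 0.2, c = 0.6)
  implied <- build_implied_cov(tr, pair_type = "DZ")
  mc <- monte_carlo_implied_cov(tr, "DZ", 150000)
  se <- sqrt(2 / 150000) * 3          # generous bound for covariance entries
  expect_lt(max(abs(implied$cov - mc)), 3 * se + 0.01)
})

test_that("a structural feedback loop with unit total effect is an error", {
  mod <- path_model("biDir", mediators = character())
  vc <- list(te = variance_components(0.3, 0.2, 0.5, 0),
             ptsdsx = variance_components(0.3, 0.2, 0.5, 0))
  expect_error(
    build_implied_cov(mod, list(paths = c(c = 2, c_rev = 0.5),
                                components = vc), "MZ"),
    "feedback")
})

test_that("FIML matches the Gaussian MLE identity on complete univariate data", {
  set.seed(401)
  n <- 400
  y <- rnorm(n, 1.5, 1.2)
  d <- data.frame(person_id = seq_len(n), family_id = paste0("F", seq_len(n)),
                  site_id = "S1", relation = "SINGLETON", y = y)
  fd <- fiml_data(d, c(te = "y"))
  mu_hat <- mean(y)
  s2_hat <- mean((y - mu_hat)^2)
  prm <- list(mu = mu_hat, paths = numeric(0),
              components = list(te = variance_components(1e-12, 0, s2_hat, 0)))
  m2ll <- fiml_neg2ll(variance_model("te"), prm, fd)
  expect_equal(m2ll, n * (log(2 * pi) + log(s2_hat) + 1), tolerance = 1e-8)
})

test_that("a fully missing member marginalizes to the reduced cluster", {
  set.seed(403)
  tr <- small_truth()
  g <- generate_cohort(plain_spec(n_mz = 30, n_dz = 30, seed = 405), tr)
  co <- scores_from_cohort(g$cohort, "roi_1")
  cols <- c(te = "te_score", roi_1 = "roi_1_std", ptsdsx = "ptsdsx_score")
  co2 <- co
  drop_ids <- co2$person_id[seq(2, 20, by = 2)]
  co2[co2$person_id %in% drop_ids, cols] <- NA
  co3 <- co[!co$person_id %in% drop_ids, ]
  mod <- path_model("uniDir", mediators = "roi_1")
  prm <- list(mu = c(0, 0, 0), paths = c(a_roi_1 = 0.2, b_roi_1 = 0.25, c = 0.5),
              components = lapply(tr$components[c("te", "roi_1", "ptsdsx")],
                                  function(z) z))
  names(prm$components) <- c("te", "roi_1", "ptsdsx")
  v2 <- fiml_neg2ll(mod, prm, fiml_data(co2, cols))
  v3 <- fiml_neg2ll(mod, prm, fiml_data(co3, cols))
  expect_equal(v2, v3, tolerance = 1e-8)
})

test_that("FIML equals the brute-force marginal density under random missingness", {
  set.seed(407)
  # var_S = 0 throughout, so families are independent clusters and the
  # likelihood factorizes over pairs
  tr <- truth_record(mediators = "roi_1", a = 0.2, b = 0.25, c = 0.5,
                     te_mix = c(0.3, 0.3, 0.4, 0),
                     mediator_mix = c(0.5, 0.25, 0.25, 0),
                     ptsdsx_mix = c(0.3, 0.2, 0.5, 0))
  g <- generate_cohort(plain_spec(n_mz = 12, n_dz = 12, n_sites = 4,
                                  seed = 409), tr)
  co <- scores_from_cohort(g$cohort, "roi_1")
  cols <- c(te = "te_score", roi_1 = "roi_1_std", ptsdsx = "ptsdsx_score")
  sc <- as.matrix(co[, cols])
  sc[matrix(runif(length(sc)) < 0.3, nrow(sc))] <- NA
  co[, cols] <- sc
  mod <- path_model("uniDir", mediators = "roi_1")
  comps <- tr$components[c("te", "roi_1", "ptsdsx")]
  prm <- list(mu = c(0.1, -0.2, 0.05),
              paths = c(a_roi_1 = 0.18, b_roi_1 = 0.22, c = 0.45),
              components = comps)
  fast <- fiml_neg2ll(mod, prm, fiml_data(co, cols))

  # oracle: stack each family as one 6-vector and evaluate the observed
  # subvector against the implied pair covariance directly
  pair_rows <- list(); mu_all <- list()
  for (f in unique(co$family_id)) {
    members <- co[co$family_id == f, ]
    ptype <- members$relation[1]
    implied <- build_implied_cov(mod, prm, ptype)
    row <- as.numeric(t(as.matrix(members[, cols])))
    keep <- !all(is.na(row))
    if (keep) {
      pair_rows[[f]] <- row
      mu_all[[f]] <- implied$mean
    }
  }
  implied_mz <- build_implied_cov(mod, prm, "MZ")
  implied_dz <- build_implied_cov(mod, prm, "DZ")
  slow <- 0
  for (f in names(pair_rows)) {
    ptype <- co$relation[co$family_id == f][1]
    sigma <- if (ptype == "MZ") implied_mz$cov else implied_dz$cov
    slow <- slow + brute_mvn_m2ll(pair_rows[f], rep(prm$mu, 2), sigma)
  }
  expect_equal(fast, slow, tolerance = 1e-8)
})

test_that("the site term is evaluated exactly (Woodbury vs full joint density)", {
  set.seed(411)
  tr <- truth_record(te_mix = c(0.3, 0.25, 0.35, 0.1))
  g <- generate_cohort(plain_spec(n_mz = 6, n_dz = 6, n_sing = 8,
                                  n_sites = 2, seed = 413), tr)
  co <- scores_from_cohort(g$cohort)
  co$te_score[3] <- NA
  fd <- fiml_data(co, c(te = "te_score"))
  vc <- list(te = variance_components(0.3, 0.25, 0.35, 0.1))
  prm <- list(mu = 0.05, paths = numeric(0), components = vc)
  fast <- fiml_neg2ll(variance_model("te"), prm, fd)

  # oracle: build every site's full joint covariance explicitly
  slow <- 0
  for (s in unique(co$site_id)) {
    d <- co[co$site_id == s, ]
    n <- nrow(d)
    S <- matrix(0.1, n, n)                      # shared site variance
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) S[i, j] <- 0.3 + 0.25 + 0.35 + 0.1
      else if (d$family_id[i] == d$family_id[j]) {
        r <- if (d$relation[i] == "MZ") 1 else 0.5
        S[i, j] <- r * 0.3 + 0.25 + 0.1
      }
    }
    slow <- slow + brute_mvn_m2ll(list(d$te_score), rep(0.05, n), S)
  }
  expect_equal(fast, slow, tolerance = 1e-8)
})

test_that("the likelihood surface is centered near the generating parameters", {
  set.seed(415)
  tr <- truth_record(te_mix = c(0.4, 0.3, 0.28, 0.02))
  g <- generate_cohort(plain_spec(n_mz = 800, n_dz = 800, seed = 417), tr)
  co <- scores_from_cohort(g$cohort)
  fd <- fiml_data(co, c(te = "te_score"))
  mod <- variance_model("te")
  at <- function(va) fiml_neg2ll(mod, list(
    mu = 0, paths = numeric(0),
    components = list(te = variance_components(va, 0.3, 0.28, 0.02))), fd)
  expect_lt(at(0.4), at(0.1))
  expect_lt(at(0.4), at(0.7))
})

test_that("ML fit recovers a zero site component and responds to model nesting", {
  set.seed(419)
  tr <- truth_record(te_mix = c(0.45, 0.25, 0.299, 0.001))
  g <- generate_cohort(plain_spec(n_mz = 600, n_dz = 600, n_sing = 800,
                                  n_sites = 8, seed = 421), tr)
  co <- scores_from_cohort(g$cohort)
  fd <- fiml_data(co, c(te = "te_score"))
  fit <- fit_ml(variance_model("te"), fd, n_starts = 1, ci = "none")
  expect_lt(fit$estimates[["te.var_S"]], 0.02)
  expect_equal(fit$aic, fit$minus2ll - 2 * fit$df)   # AIC identity
  expect_lt(abs(fit$estimates[["te.var_A"]] - 0.45), 0.12)
})

test_that("richer variants never fit worse than their nested counterparts", {
  set.seed(423)
  tr <- small_truth(a = 0.15, b = 0.2, c = 0.5)
  g <- generate_cohort(plain_spec(n_mz = 250, n_dz = 250, n_sing = 300,
                                  seed = 425), tr)
  co <- scores_from_cohort(g$cohort, "roi_1")
  fd <- fiml_data(co, c(te = "te_score", roi_1 = "roi_1_std",
                        ptsdsx = "ptsdsx_score"))
  uni <- fit_ml(path_model("uniDir", "roi_1"), fd, n_starts = 1, ci = "none")
  bi <- fit_ml(path_model("biDir", "roi_1"), fd, n_starts = 1, ci = "none")
  expect_lte(bi$minus2ll, uni$minus2ll + 1e-4)
  expect_equal(bi$ep, uni$ep + 1)
  expect_equal(uni$aic, uni$minus2ll - 2 * uni$df)
})

test_that("trivariate path recovery under the unidirectional truth", {
  set.seed(427)
  tr <- small_truth(a = 0.2, b = 0.25, c = 0.5)
  g <- generate_cohort(plain_spec(n_mz = 500, n_dz = 500, n_sing = 700,
                                  seed = 429), tr)
  co <- scores_from_cohort(g$cohort, "roi_1")
  fd <- fiml_data(co, c(te = "te_score", roi_1 = "roi_1_std",
                        ptsdsx = "ptsdsx_score"))
  fit <- fit_ml(path_model("uniDir", "roi_1"), fd, n_starts = 1, ci = "delta")
  expect_lt(abs(fit$estimates[["c"]] - 0.5), 0.06)
  expect_lt(abs(fit$estimates[["a_roi_1"]] - 0.2), 0.07)
  expect_lt(abs(fit$estimates[["b_roi_1"]] - 0.25), 0.07)
  # delta-method intervals bracket their estimates
  ci <- fit$ci
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  # indirect effect from the fitted object carries a CI
  ie <- indirect_effect(fit, "roi_1")
  expect_equal(ie$estimate,
               fit$estimates[["a_roi_1"]] * fit$estimates[["b_roi_1"]])
  expect_true(ie$lower <= ie$estimate && ie$estimate <= ie$upper)
})

test_that("indirect effects reproduce the printed worked examples", {
  # right lateral ventricle: a and b paths as printed
  expect_equal(signif(indirect_effect(-0.009, -0.008)$estimate, 1), 7e-05)
  # left anterior transverse collateral sulcus
  expect_equal(signif(indirect_effect(-0.015, -0.021)$estimate, 1), 3e-04)
  expect_equal(indirect_effect(0, 0.5)$estimate, 0)
})

test_that("variance proportions standardize and delta intervals are sane", {
  vc <- variance_components(0.25, 0.25, 0.25, 0.25)
  pr <- standardize_components(vc)
  expect_equal(pr$proportion, rep(0.25, 4))
  vc2 <- variance_components(0.5, 0.2, 0.4, 0.05)
  pr2 <- standardize_components(vc2, vcov = diag(4) * 1e-4)
  expect_equal(sum(pr2$proportion), 1)
  expect_true(all(pr2$lower <= pr2$proportion & pr2$proportion <= pr2$upper))
})

test_that("saturated twin correlations match moments and the generating values", {
  set.seed(431)
  tr <- truth_record(te_mix = c(0.8, 1e-6, 0.2, 1e-6))
  g <- generate_cohort(plain_spec(n_mz = 900, n_dz = 900, seed = 433), tr)
  co <- scores_from_cohort(g$cohort)
  tw <- twin_saturated_correlations(co, c(te = "te_score"))
  expect_lt(abs(tw$mz$cor["te_T1", "te_T2"] - 0.8), 0.05)
  expect_lt(abs(tw$dz$cor["te_T1", "te_T2"] - 0.4), 0.07)
  expect_equal(diag(tw$combined), c(te_T1 = 1, te_T2 = 1))
  expect_true(tw$mz$lower["te_T1", "te_T2"] <= tw$mz$cor["te_T1", "te_T2"])
  # tiny groups give a warning per zygosity group and missing entries
  w <- capture_warnings(
    tw_small <- twin_saturated_correlations(co[1:4, ], c(te = "te_score")))
  expect_true(all(grepl("fewer than 3", w)))
  expect_null(tw_small$combined)
})

test_that("penalized path fits shrink mediator paths but keep the direct path", {
  set.seed(435)
  tr <- small_truth(a = 0.25, b = 0.3, c = 0.5)
  g <- generate_cohort(plain_spec(n_mz = 200, n_dz = 200, seed = 437), tr)
  co <- scores_from_cohort(g$cohort, "roi_1")
  fd <- fiml_data(co, c(te = "te_score", roi_1 = "roi_1_std",
                        ptsdsx = "ptsdsx_score"))
  mod <- path_model("uniDir", "roi_1")
  big <- penalized_path_fit(mod, fd, lambda = 5000, alpha = 1, n_starts = 1)
  expect_lt(abs(big$estimates[["a_roi_1"]]), 0.02)
  expect_lt(abs(big$estimates[["b_roi_1"]]), 0.02)
  expect_gt(big$estimates[["c"]], 0.3)
  none <- penalized_path_fit(mod, fd, lambda = 0, alpha = 1, n_starts = 1)
  ml <- fit_ml(mod, fd, n_starts = 1, ci = "none")
  expect_equal(none$minus2ll, ml$minus2ll, tolerance = 1e-4)
  expect_equal(none$estimates[["c"]], ml$estimates[["c"]], tolerance = 1e-3)
})

test_that("profile likelihood intervals bracket the estimate on a small fit", {
  set.seed(439)
  tr <- truth_record(te_mix = c(0.4, 0.3, 0.29, 0.01))
  g <- generate_cohort(plain_spec(n_mz = 150, n_dz = 150, seed = 441), tr)
  co <- scores_from_cohort(g$cohort)
  fd <- fiml_data(co, c(te = "te_score"))
  fit <- fit_ml(variance_model("te"), fd, n_starts = 1)
  pc <- profile_ci(fit, "te.var_A", fd)
  expect_lt(pc$lower, fit$internal_par[[match("te.var_A", fit$map$names)]])
  expect_gt(pc$upper, fit$internal_par[[match("te.var_A", fit$map$names)]])
})
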