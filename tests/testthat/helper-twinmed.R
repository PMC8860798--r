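# shared fixtures and independent oracles, built in code at test time

# brute-force -2 log-likelihood: per cluster, take the observed submatrix of
# the implied covariance and evaluate the multivariate-normal density
# directly with solve()/determinant() -- no pattern pooling, no Woodbury
brute_mvn_m2ll <- function(rows, mu, sigma) {
  total <- 0
  for (r in rows) {
    obs <- which(!is.na(r))
    x <- r[obs] - mu[obs]
    S <- sigma[obs, obs, drop = FALSE]
    ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
    total <- total + ld + as.numeric(t(x) %*% solve(S, x)) +
      length(obs) * log(2 * pi)
  }
  total
}

# standard small trivariate mediation truth used across tests
small_truth <- function(a = 0.2, b = 0.25, c = 0.5) {
  truth_record(mediators = "roi_1", a = a, b = b, c = c,
               te_mix = c(0.3, 0.3, 0.38, 0.02),
               mediator_mix = c(0.5, 0.25, 0.23, 0.02),
               ptsdsx_mix = c(0.3, 0.2, 0.48, 0.02))
}

# cohort with covariate effects and nuisance switched off, for tests that
# look at the latent liabilities directly
plain_spec <- function(n_mz = 500, n_dz = 500, n_sing = 0, n_sites = 4,
                       seed = 1) {
  cohort_spec(n_mz_pairs = n_mz, n_dz_pairs = n_dz, n_singletons = n_sing,
              n_sites = n_sites, n_twin_hub_sites = min(4, n_sites),
              covariate_model = list(age = 0, sex = 0, ancestry = 0,
                                     scanner = 0, total_volume = 0),
              zero_te_target = NULL, qc_fail_rate = 0, outlier_rate = 0,
              seed = seed)
}

# residualize + standardize the liabilities and one ROI, returning a table
# ready for fiml_data()
scores_from_cohort <- function(cohort, roi = NULL) {
  cv <- cohort[, c("age", "sex", "ancestry")]
  cohort$te_score <- residualize_standardize(cohort$te_liability, cv)
  cohort$ptsdsx_score <- residualize_standardize(cohort$ptsdsx_liability, cv)
  if (!is.null(roi))
    cohort[[paste0(roi, "_std")]] <- residualize_standardize(
      cohort[[roi]], cbind(cv, scanner = cohort$scanner,
                           total = cohort$total_subcortical_volume))
  cohort
}

# cross-twin covariance of a per-person vector, pairs stored consecutively
cross_twin_cov <- function(x, relation, type) {
  i1 <- which(relation == type)[c(TRUE, FALSE)]
  stats::cov(x[i1], x[i1 + 1])
}
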