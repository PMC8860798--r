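#' Generate a synthetic family-and-site clustered cohort
#'
#' Simulates a cohort with the covariance structure the downstream models
#' assume: additive-genetic (A) latent components correlate 1.0 within MZ
#' pairs and 0.5 within DZ and full-sibling pairs, shared-environmental (C)
#' components are common to a family, site (S) components are common to all
#' members of a study site, and unique-environmental (E) components are
#' person-specific. Structural mediation paths are applied on the liability
#' scale (`M_j = a_j X + u_j`, `Y = c X + sum b_j M_j + u_Y`, generalized
#' through the path matrix so reverse paths are supported), binary
#' traumatic-event and PTSD-symptom items are produced from the liabilities
#' through two-parameter logistic response curves, and covariate, scanner,
#' total-volume, QC and outlier nuisance is layered on the observed columns.
#'
#' Columns `te_liability` and `ptsdsx_liability` carry the generating latent
#' scores; they exist for parameter-recovery studies only and have no
#' counterpart in real data.
#'
#' @param spec a [cohort_spec()].
#' @param truth a [truth_record()].
#' @return A list with elements `cohort` (a `cohort_table` data.frame) and
#'   `truth` (the truth record, with the calibrated item-difficulty shift
#'   recorded in `truth$te_difficulty_shift`).
#' @export
generate_cohort <- function(spec, truth) {
  if (!inherits(spec, "cohort_spec")) stop_field("spec", "must be a cohort_spec")
  if (!inherits(truth, "truth_record")) stop_field("truth", "must be a truth_record")
  set.seed(spec$seed)

  fam <- data.frame(
    type = rep(c("MZ", "DZ", "SIB", "SINGLETON"),
               c(spec$n_mz_pairs, spec$n_dz_pairs,
                 spec$n_sib_pairs, spec$n_singletons)),
    stringsAsFactors = FALSE
  )
  n_fam <- nrow(fam)
  fam$id <- sprintf("F%05d", seq_len(n_fam))
  twin <- fam$type %in% c("MZ", "DZ")
  fam$site <- NA_integer_
  fam$site[twin] <- rep_len(seq_len(spec$n_twin_hub_sites), sum(twin))
  fam$site[!twin] <- rep_len(seq_len(spec$n_sites), sum(!twin))

  members <- ifelse(fam$type == "SINGLETON", 1L, 2L)
  idx <- rep(seq_len(n_fam), members)
  n <- length(idx)
  persons <- data.frame(
    person_id = sprintf("P%06d", seq_len(n)),
    family_id = fam$id[idx],
    site_id = sprintf("S%02d", fam$site[idx]),
    relation = fam$type[idx],
    stringsAsFactors = FALSE
  )

  phen <- truth$phenotypes
  p <- length(phen)
  r_person <- ifelse(persons$relation == "MZ", 1,
                     ifelse(persons$relation == "SINGLETON", 0, 0.5))

  draw <- draw_component_scores(truth, n, idx, fam$site, r_person,
                                n_sites = spec$n_sites)
  G <- path_solve(truth$B)
  scores <- draw %*% t(G)
  colnames(scores) <- phen

  # covariates: age in years, sex shared within twin pairs, ancestry shared
  # within family, scanner fixed per site (3 models)
  age <- stats::runif(n, 9, 11)
  sex_fam <- stats::rbinom(n_fam, 1, 0.5)
  sex <- ifelse(persons$relation %in% c("MZ", "DZ"),
                sex_fam[idx], stats::rbinom(n, 1, 0.5))
  anc_levels <- c("white", "black", "hispanic", "asian", "other")
  anc_fam <- sample(anc_levels, n_fam, replace = TRUE,
                    prob = c(0.52, 0.15, 0.20, 0.02, 0.11))
  ancestry <- anc_fam[idx]
  scanner_site <- sample(c("siemens", "ge", "philips"), spec$n_sites,
                         replace = TRUE)
  scanner <- scanner_site[fam$site[idx]]

  cm <- spec$covariate_model
  anc_off <- (cm$ancestry %||% 0) *
    c(white = -1, black = -0.5, hispanic = 0, asian = 0.5, other = 1)[ancestry]
  cov_shift <- (cm$age %||% 0) * (age - 10) + (cm$sex %||% 0) * (sex - 0.5) +
    anc_off
  scan_off <- (cm$scanner %||% 0) *
    c(siemens = -1, ge = 0, philips = 1)[scanner]

  totals <- draw_family_trait(n, idx, n_fam, 2)
  colnames(totals) <- c("total_subcortical_volume", "total_cortical_volume")

  cohort <- persons
  cohort$age <- age
  cohort$sex <- sex
  cohort$ancestry <- ancestry
  cohort$scanner <- scanner

  shift <- 0
  if (!is.null(spec$zero_te_target))
    shift <- calibrate_difficulty_shift(truth$te_items, spec$zero_te_target)
  te_items <- truth$te_items
  te_items$difficulty <- te_items$difficulty + shift
  te_resp <- generate_item_responses(scores[, "te"], te_items)
  colnames(te_resp) <- sprintf("te_item_%02d", seq_len(nrow(te_items)))
  px_resp <- generate_item_responses(scores[, "ptsdsx"], truth$ptsdsx_items)
  colnames(px_resp) <- sprintf("ptsd_item_%02d", seq_len(nrow(truth$ptsdsx_items)))

  cohort <- cbind(cohort, as.data.frame(te_resp), as.data.frame(px_resp))
  for (m in truth$mediators)
    cohort[[m]] <- scores[, m] + cov_shift + scan_off +
      (cm$total_volume %||% 0) * totals[, "total_subcortical_volume"]
  cohort$total_subcortical_volume <- totals[, "total_subcortical_volume"]
  cohort$total_cortical_volume <- totals[, "total_cortical_volume"]
  cohort$te_liability <- scores[, "te"] + cov_shift
  cohort$ptsdsx_liability <- scores[, "ptsdsx"] + cov_shift

  cohort <- inject_missingness_and_outliers(cohort, spec,
                                            roi_cols = truth$mediators)
  class(cohort) <- c("cohort_table", "data.frame")
  truth$te_difficulty_shift <- shift
  list(cohort = cohort, truth = truth)
}

# latent A/C/E/S component draws for all phenotypes, with contralateral
# cross-phenotype correlations entering through the component chol factors
draw_component_scores <- function(truth, n, idx, fam_site, r_person, n_sites) {
  phen <- truth$phenotypes
  p <- length(phen)
  ch <- function(component) {
    R <- diag(p); dimnames(R) <- list(phen, phen)
    ctr <- truth$contralateral
    rcol <- c(var_A = "rA", var_C = "rC", var_E = "rE")[component]
    if (!is.null(ctr) && !is.na(rcol)) {
      for (i in seq_len(nrow(ctr)))
        R[ctr$left[i], ctr$right[i]] <- R[ctr$right[i], ctr$left[i]] <- ctr[[rcol]][i]
    }
    chol(R)
  }
  n_fam <- max(idx)
  std <- function(nr, L) matrix(stats::rnorm(nr * p), nr, p) %*% L

  LA <- ch("var_A")
  a_shared <- std(n_fam, LA)[idx, , drop = FALSE]
  a_unique <- std(n, LA)
  w <- sqrt(pmax(0, r_person))
  A <- w * a_shared + sqrt(1 - r_person) * a_unique
  C <- std(n_fam, ch("var_C"))[idx, , drop = FALSE]
  E <- std(n, ch("var_E"))
  S <- matrix(stats::rnorm(n_sites * p), n_sites, p)[fam_site[idx], , drop = FALSE]

  sd_of <- function(component)
    sqrt(vapply(truth$components, function(z) max(z[[component]], 0), numeric(1)))
  u <- A %*% diag(sd_of("var_A"), p) + C %*% diag(sd_of("var_C"), p) +
    E %*% diag(sd_of("var_E"), p) + S %*% diag(sd_of("var_S"), p)
  colnames(u) <- phen
  u
}

# simple family-structured unit-variance nuisance traits (used for the
# total-volume covariates): A = 0.6, C = 0.2, E = 0.2
draw_family_trait <- function(n, idx, n_fam, k) {
  a_sh <- matrix(stats::rnorm(n_fam * k), n_fam, k)[idx, , drop = FALSE]
  c_sh <- matrix(stats::rnorm(n_fam * k), n_fam, k)[idx, , drop = FALSE]
  e <- matrix(stats::rnorm(n * k), n, k)
  sqrt(0.6) * a_sh + sqrt(0.2) * c_sh + sqrt(0.2) * e
}

#' Generate binary item responses from a two-parameter logistic model
#'
#' The endorsement probability given liability `theta` follows the 2PL
#' response curve; it equals exactly 0.5 where `theta` equals the item's
#' difficulty.
#'
#' @param liability numeric vector of person liabilities (theta scale).
#' @param item_params data.frame with columns `discrimination` (> 0) and
#'   `difficulty`.
#' @return Integer matrix (persons x items) of 0/1 responses.
#' @export
generate_item_responses <- function(liability, item_params) {
  item_params <- validate_items(item_params, "item_params")
  n <- length(liability)
  k <- nrow(item_params)
  pr <- outer(liability, seq_len(k), function(th, j)
    logistic_2pl(th, item_params$discrimination[j], item_params$difficulty[j]))
  resp <- matrix(as.integer(stats::runif(n * k) < pr), n, k)
  resp
}

# common difficulty shift delta so that P(no endorsed item) over a standard
# normal liability hits the target zero-endorsement proportion
calibrate_difficulty_shift <- function(item_params, target) {
  q <- normal_quadrature(61)
  p_zero <- function(delta) {
    pm <- outer(q$nodes, seq_len(nrow(item_params)), function(th, j)
      logistic_2pl(th, item_params$discrimination[j],
                   item_params$difficulty[j] + delta))
    sum(q$weights * exp(rowSums(log1p(-pm))))
  }
  lo <- -6; hi <- 6
  if (p_zero(lo) > target || p_zero(hi) < target)
    stop("zero_te_target is unreachable with these item parameters")
  stats::uniroot(function(d) p_zero(d) - target, c(lo, hi), tol = 1e-8)$root
}

#' Inject MRI quality-control failures and ROI outliers
#'
#' Draws a QC score whose configured fraction falls below the conventional
#' threshold of 600 frames, and replaces a configured fraction of ROI
#' datapoints with values beyond 4 SD of their column. Deterministic given
#' the RNG state; [generate_cohort()] applies it under the spec seed.
#'
#' @param table a cohort data.frame.
#' @param spec a [cohort_spec()] carrying `qc_fail_rate` and `outlier_rate`.
#' @param roi_cols character vector of ROI volume column names.
#' @return The table with a `qc_score` column and outliers injected.
#' @export
inject_missingness_and_outliers <- function(table, spec, roi_cols) {
  n <- nrow(table)
  rate <- max(spec$qc_fail_rate, 1e-12)
  table$qc_score <- 600 + 150 * (stats::rnorm(n) - stats::qnorm(rate))
  if (spec$outlier_rate > 0) {
    for (col in roi_cols) {
      hit <- stats::runif(n) < spec$outlier_rate
      if (any(hit)) {
        s <- stats::sd(table[[col]], na.rm = TRUE)
        m <- mean(table[[col]], na.rm = TRUE)
        table[[col]][hit] <- m + sample(c(-1, 1), sum(hit), replace = TRUE) *
          (4.2 + stats::rexp(sum(hit), 2)) * s
      }
    }
  }
  table
}

#' Monte-Carlo oracle for the model-implied pair covariance
#'
#' Brute-force simulation of (member 1, member 2) phenotype vectors under
#' the generating parameters, sharing components according to the pair type.
#' Serves as the simulation oracle against which [build_implied_cov()] is
#' checked: the empirical covariance converges to the model-implied one as
#' `n_replicates` grows.
#'
#' @param truth a [truth_record()].
#' @param pair_type one of `"MZ"`, `"DZ"`, `"SIB"`, `"unrelated_same_site"`,
#'   `"singleton"`.
#' @param n_replicates number of simulated pairs (at least 1000).
#' @return The empirical covariance matrix of the stacked pair vector
#'   (2p x 2p, or p x p for `"singleton"`).
#' @export
monte_carlo_implied_cov <- function(truth, pair_type, n_replicates = 100000) {
  if (n_replicates < 1000) stop_field("n_replicates", "must be at least 1000")
  share <- switch(pair_type,
    MZ = c(r = 1, fam = 1, site = 1),
    DZ = c(r = 0.5, fam = 1, site = 1),
    SIB = c(r = 0.5, fam = 1, site = 1),
    unrelated_same_site = c(r = 0, fam = 0, site = 1),
    singleton = NULL,
    stop_field("pair_type", "unknown pair type")
  )
  phen <- truth$phenotypes
  p <- length(phen)
  G <- path_solve(truth$B)
  nrep <- n_replicates
  if (pair_type == "singleton") {
    idx <- seq_len(nrep)
    u <- draw_component_scores(truth, nrep, idx, rep(1L, nrep), rep(0, nrep), 1)
    return(stats::cov(u %*% t(G)))
  }
  if (share[["fam"]] == 0) {
    # unrelated, same site: every person is their own family, pairs share
    # only the site draw
    u <- draw_component_scores(truth, 2 * nrep, idx = seq_len(2 * nrep),
                               fam_site = rep(seq_len(nrep), each = 2),
                               r_person = rep(0, 2 * nrep), n_sites = nrep)
  } else {
    # one family per pair, one site per family
    u <- draw_component_scores(truth, 2 * nrep,
                               idx = rep(seq_len(nrep), each = 2),
                               fam_site = seq_len(nrep),
                               r_person = rep(share[["r"]], 2 * nrep),
                               n_sites = nrep)
  }
  pp <- u %*% t(G)
  wide <- cbind(pp[seq(1, 2 * nrep, by = 2), , drop = FALSE],
                pp[seq(2, 2 * nrep, by = 2), , drop = FALSE])
  colnames(wide) <- c(paste0(phen, "_1"), paste0(phen, "_2"))
  stats::cov(wide)
}

#' Write / read a cohort with its generating metadata
#'
#' The cohort is written as a plain CSV and the truth record, spec and seed
#' as a JSON sidecar (`<path>.meta.json`), so a run can be reproduced or
#' consumed outside R.
#'
#' @param cohort a cohort data.frame.
#' @param path output CSV path.
#' @param truth optional [truth_record()] stored in the sidecar.
#' @param spec optional [cohort_spec()] stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth = NULL, spec = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE)
  meta <- list(
    spec = if (!is.null(spec)) unclass(spec),
    truth = if (!is.null(truth)) serialize_truth(truth)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

serialize_truth <- function(truth) {
  list(
    phenotypes = truth$phenotypes,
    mediators = truth$mediators,
    paths = truth$paths,
    components = lapply(truth$components, unclass),
    contralateral = truth$contralateral,
    te_items = truth$te_items,
    ptsdsx_items = truth$ptsdsx_items,
    link = truth$link,
    te_difficulty_shift = truth$te_difficulty_shift %||% 0
  )
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}
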