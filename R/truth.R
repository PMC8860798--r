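#' Generating parameters of a synthetic cohort
#'
#' Builds the ground-truth record used by [generate_cohort()]: the structural
#' mediation paths, the variance-component composition of every phenotype,
#' contralateral (left/right homologue) component correlations, and the item
#' parameters that turn the two liabilities into binary responses.
#'
#' Phenotypes live on the standardized liability scale. The traumatic-events
#' liability (`te`) is the exposure, mediator phenotypes are ROI volumes, and
#' the PTSD-symptom liability (`ptsdsx`) is the outcome. Component mixes are
#' supplied as proportions (they are normalized to sum to one); the
#' constructor then scales each phenotype's residual components so that every
#' phenotype has unit total variance under the requested paths. Mediator and
#' outcome mixes therefore describe the *residual* composition, matching the
#' residual-A/C/E/S convention for an outcome with upstream causes.
#'
#' @param mediators character vector of mediator (ROI) phenotype names.
#' @param a,b standardized exposure-to-mediator and mediator-to-outcome path
#'   coefficients, one per mediator.
#' @param c standardized direct path from exposure to outcome.
#' @param c_rev,a_rev,b_rev reverse-direction paths (outcome to exposure /
#'   mediators); zero in the unidirectional model.
#' @param te_mix,ptsdsx_mix length-4 vectors of A/C/E/S proportions for the
#'   exposure liability and the outcome residual.
#' @param mediator_mix a length-4 vector applied to every mediator, or a
#'   matrix/data.frame with one row per mediator (columns A, C, E, S).
#' @param contralateral optional data.frame with columns `left`, `right`,
#'   `rA`, `rC`, `rE` giving component correlations between homologous ROIs.
#' @param te_items,ptsdsx_items data.frames with columns `discrimination`
#'   and `difficulty` (theta-scale SD units) for the binary items; defaults
#'   emulate rare-event trauma items, most with difficulty at or above +2 SD.
#' @param link response-curve link for item generation; logistic 2PL.
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(mediators = character(),
                         a = numeric(), b = numeric(), c = 0,
                         c_rev = 0, a_rev = NULL, b_rev = NULL,
                         te_mix = c(A = 0.23, C = 0.62, E = 0.15, S = 0.01),
                         ptsdsx_mix = c(A = 0.21, C = 0.18, E = 0.22, S = 0.005),
                         mediator_mix = c(A = 0.5, C = 0.25, E = 0.24, S = 0.01),
                         contralateral = NULL,
                         te_items = default_te_items(),
                         ptsdsx_items = default_ptsdsx_items(),
                         link = "logit") {
  k <- length(mediators)
  if (length(a) != k || length(b) != k)
    stop_field("a/b", "must have one entry per mediator")
  if (k > 0 && any(abs(a) >= 1))
    stop_field("a", "absolute a-paths must be < 1 on the standardized scale")
  phenotypes <- c("te", mediators, "ptsdsx")
  paths <- list(a = a, b = b, c = c, c_rev = c_rev,
                a_rev = a_rev %||% rep(0, k), b_rev = b_rev %||% rep(0, k))
  B <- build_path_matrix(paths, phenotypes)
  G <- path_solve(B)

  norm_mix <- function(m, field) {
    m <- as.numeric(m)
    if (length(m) != 4 || any(!is.finite(m)) || any(m < 0) || m[3] <= 0)
      stop_field(field, "must be 4 non-negative proportions (A,C,E,S) with E > 0")
    m / sum(m)
  }
  mixes <- matrix(0, length(phenotypes), 4,
                  dimnames = list(phenotypes, component_names))
  mixes["te", ] <- norm_mix(te_mix, "te_mix")
  mixes["ptsdsx", ] <- norm_mix(ptsdsx_mix, "ptsdsx_mix")
  if (k > 0) {
    if (is.null(dim(mediator_mix))) {
      mm <- matrix(rep(norm_mix(mediator_mix, "mediator_mix"), each = k), k, 4)
    } else {
      mm <- t(apply(as.matrix(mediator_mix), 1, norm_mix, field = "mediator_mix"))
      if (nrow(mm) != k) stop_field("mediator_mix", "needs one row per mediator")
    }
    mixes[mediators, ] <- mm
  }
  if (!is.null(contralateral)) {
    need <- c("left", "right", "rA", "rC", "rE")
    if (!all(need %in% names(contralateral)))
      stop_field("contralateral", "needs columns left, right, rA, rC, rE")
    if (any(abs(unlist(contralateral[c("rA", "rC", "rE")])) > 1))
      stop_field("contralateral", "correlations must lie in [-1, 1]")
    if (!all(c(contralateral$left, contralateral$right) %in% mediators))
      stop_field("contralateral", "pair names must be mediator names")
  }

  # scale residual variances so each phenotype has unit total variance:
  # diag(G Psi(v) G') = 1 solved by damped Newton on the per-phenotype
  # residual scale (cross terms from contralateral correlations are small)
  v <- rep(1, length(phenotypes)); names(v) <- phenotypes
  G2 <- G * G
  for (iter in 1:200) {
    vc_list <- make_vc_list(v, mixes)
    psi <- psi_total(vc_list, contralateral)
    tot <- diag(G %*% psi %*% t(G))
    if (max(abs(tot - 1)) < 1e-12) break
    cross <- tot - as.numeric(G2 %*% v)   # contralateral contribution
    v_new <- solve(G2, 1 - cross)
    if (any(v_new <= 0))
      stop("paths explain all the variance of a phenotype; reduce |a|, |b| or |c|")
    v <- 0.5 * v + 0.5 * as.numeric(v_new); names(v) <- phenotypes
  }

  structure(list(
    phenotypes = phenotypes, mediators = mediators,
    paths = paths, B = B,
    components = make_vc_list(v, mixes),
    contralateral = contralateral,
    te_items = validate_items(te_items, "te_items"),
    ptsdsx_items = validate_items(ptsdsx_items, "ptsdsx_items"),
    link = link
  ), class = "truth_record")
}

make_vc_list <- function(v, mixes) {
  out <- lapply(rownames(mixes), function(ph) {
    m <- mixes[ph, ] * v[[ph]]
    variance_components(m[1], m[2], max(m[3], 1e-12), m[4])
  })
  names(out) <- rownames(mixes)
  out
}

psi_total <- function(vc_list, contralateral = NULL) {
  psi_component(vc_list, "var_A", contralateral) +
    psi_component(vc_list, "var_C", contralateral) +
    psi_component(vc_list, "var_E", contralateral) +
    psi_component(vc_list, "var_S", contralateral)
}

validate_items <- function(items, field) {
  items <- as.data.frame(items)
  if (!all(c("discrimination", "difficulty") %in% names(items)))
    stop_field(field, "needs columns discrimination and difficulty")
  if (any(!is.finite(items$discrimination)) || any(!is.finite(items$difficulty)))
    stop_field(field, "item parameters must be finite")
  if (any(items$discrimination <= 0))
    stop_field(field, "discriminations must be positive")
  items
}

#' Default traumatic-event item parameters
#'
#' 17 binary criterion-A items on the liability (theta) scale. Fifteen items
#' reach 50% endorsement only at +2 SD or more above the mean (rare direct
#' threats and interpersonal trauma, strongly discriminating); two items
#' (learning about death, witnessing home violence) sit below +2 SD with
#' weaker loadings. Standardized loadings span roughly 0.46-0.96. Under a
#' standard-normal liability these parameters give about 62% of subjects
#' with no endorsed item and about 97% with at most two, matching the
#' skewed count distribution typical of childhood trauma checklists.
#' @return data.frame with columns `discrimination`, `difficulty`.
#' @export
default_te_items <- function() {
  difficulty <- c(1.3, 1.9, seq(2.6, 5.0, length.out = 15))
  loading <- c(0.55, 0.50, seq(0.96, 0.46, length.out = 15))
  data.frame(discrimination = loading_to_discrimination(loading),
             difficulty = difficulty)
}

#' Default PTSD-symptom item parameters
#'
#' 22 binary symptom items (DSM-5 criteria beyond criterion A); difficulties
#' concentrate far in the upper tail of the liability scale, with a few
#' mood/behaviour items endorsable below +3.9 SD.
#' @return data.frame with columns `discrimination`, `difficulty`.
#' @export
default_ptsdsx_items <- function() {
  difficulty <- c(2.5, 3.0, 3.4, seq(3.9, 5.0, length.out = 19))
  loading <- seq(0.97, 0.40, length.out = 22)
  data.frame(discrimination = loading_to_discrimination(loading),
             difficulty = difficulty)
}

#' Synthetic-cohort design specification
#'
#' Describes the pedigree, site and nuisance structure of a synthetic cohort:
#' numbers of monozygotic (MZ) and dizygotic (DZ) twin pairs, full-sibling
#' pairs and singletons, the number of study sites (twin pairs are placed
#' only at `n_twin_hub_sites` hub sites, mirroring multi-site twin
#' recruitment), covariate effect sizes, the target proportion of subjects
#' endorsing no traumatic event, and the MRI quality-control failure and
#' ROI outlier rates.
#'
#' @param n_mz_pairs,n_dz_pairs,n_sib_pairs,n_singletons family-type counts.
#' @param n_sites number of study sites (default 20).
#' @param n_twin_hub_sites sites that host twin pairs (default 4).
#' @param covariate_model named list of standardized effect sizes:
#'   `age`, `sex`, `ancestry`, `scanner` (scanner affects ROI volumes only),
#'   and `total_volume` (loading of ROI volumes on the matching total).
#' @param zero_te_target proportion of subjects with no endorsed traumatic
#'   event; item difficulties are shifted by a common offset to hit it.
#'   `NULL` leaves the item difficulties as specified.
#' @param qc_fail_rate proportion of subjects with MRI QC score below 600.
#' @param outlier_rate proportion of ROI datapoints replaced by >4 SD
#'   outliers.
#' @param seed integer seed; the same spec and truth always regenerate the
#'   identical cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mz_pairs = 330, n_dz_pairs = 425,
                        n_sib_pairs = 0, n_singletons = 0,
                        n_sites = 20, n_twin_hub_sites = 4,
                        covariate_model = list(age = 0.10, sex = 0.10,
                                               ancestry = 0.05, scanner = 0.05,
                                               total_volume = 0.30),
                        zero_te_target = 0.62,
                        qc_fail_rate = 0.068, outlier_rate = 0.005,
                        seed = 1L) {
  n_mz_pairs <- check_count(n_mz_pairs, "n_mz_pairs")
  n_dz_pairs <- check_count(n_dz_pairs, "n_dz_pairs")
  n_sib_pairs <- check_count(n_sib_pairs, "n_sib_pairs")
  n_singletons <- check_count(n_singletons, "n_singletons")
  if (n_mz_pairs + n_dz_pairs + n_sib_pairs + n_singletons == 0)
    stop_field("n_mz_pairs", "at least one family type must be nonzero")
  n_sites <- check_count(n_sites, "n_sites")
  if (n_sites < 1) stop_field("n_sites", "must be at least 1")
  n_twin_hub_sites <- min(check_count(n_twin_hub_sites, "n_twin_hub_sites"),
                          n_sites)
  if (n_twin_hub_sites < 1 && (n_mz_pairs + n_dz_pairs) > 0)
    stop_field("n_twin_hub_sites", "twin pairs need at least one hub site")
  if (!is.null(zero_te_target)) check_prop(zero_te_target, "zero_te_target")
  check_prop(qc_fail_rate, "qc_fail_rate")
  check_prop(outlier_rate, "outlier_rate")
  structure(list(
    n_mz_pairs = n_mz_pairs, n_dz_pairs = n_dz_pairs,
    n_sib_pairs = n_sib_pairs, n_singletons = n_singletons,
    n_sites = n_sites, n_twin_hub_sites = n_twin_hub_sites,
    covariate_model = covariate_model,
    zero_te_target = zero_te_target,
    qc_fail_rate = qc_fail_rate, outlier_rate = outlier_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}
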