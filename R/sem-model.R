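#' Mediation path-model specification
#'
#' Defines which structural paths are free in the trivariate (exposure,
#' mediators, outcome) variance-components SEM. Variants mirror the model
#' ladder used for direction-of-causation comparison:
#' \describe{
#'   \item{`uniDir`}{paths from the exposure only: `a_j` (exposure to
#'     mediator), `b_j` (mediator to outcome), direct `c`.}
#'   \item{`biDir`}{`uniDir` plus the reverse direct path `c_rev` (outcome
#'     to exposure).}
#'   \item{`uniDir_reversed`}{paths from the outcome only: `a_rev_j`,
#'     `b_rev_j`, `c_rev`.}
#'   \item{`saturated`}{both directions free.}
#'   \item{`uniDir_no_mediation`}{direct `c` only.}
#' }
#' Every phenotype carries free A/C/E/S variance components; mediators
#' listed in `contralateral` additionally get free cross-hemisphere A/C/E
#' correlations.
#'
#' @param variant model variant name.
#' @param mediators character vector of mediator phenotype names.
#' @param contralateral optional data.frame with columns `left`, `right`
#'   naming homologous mediator pairs.
#' @return An object of class `path_model`.
#' @export
path_model <- function(variant = c("uniDir", "biDir", "uniDir_reversed",
                                   "saturated", "uniDir_no_mediation"),
                       mediators = character(), contralateral = NULL) {
  variant <- match.arg(variant)
  k <- length(mediators)
  free <- switch(variant,
    uniDir = c(if (k) c(paste0("a_", mediators), paste0("b_", mediators)), "c"),
    biDir = c(if (k) c(paste0("a_", mediators), paste0("b_", mediators)),
              "c", "c_rev"),
    uniDir_reversed = c(if (k) c(paste0("a_rev_", mediators),
                                 paste0("b_rev_", mediators)), "c_rev"),
    saturated = c(if (k) c(paste0("a_", mediators), paste0("b_", mediators),
                           paste0("a_rev_", mediators),
                           paste0("b_rev_", mediators)), "c", "c_rev"),
    uniDir_no_mediation = "c"
  )
  if (!is.null(contralateral)) {
    if (!all(c("left", "right") %in% names(contralateral)))
      stop_field("contralateral", "needs columns left and right")
    if (!all(c(contralateral$left, contralateral$right) %in% mediators))
      stop_field("contralateral", "pair names must be mediator names")
  }
  structure(list(variant = variant, mediators = mediators,
                 phenotypes = c("te", mediators, "ptsdsx"),
                 free_paths = free, contralateral = contralateral),
            class = "path_model")
}

#' Pure variance-decomposition model (no structural paths)
#'
#' A [path_model()] with no free paths: every listed phenotype gets free
#' A/C/E/S variance components and a free mean, nothing else. This is the
#' univariate (or multivariate, path-free) ACE-S model used for
#' variance-component estimation and recovery studies.
#'
#' @param phenotypes character vector of phenotype names, matching the
#'   `columns` names passed to [fiml_data()].
#' @param contralateral optional homologous-pair table as in
#'   [path_model()].
#' @return An object of class `path_model` with variant
#'   `"variance_only"`.
#' @export
variance_model <- function(phenotypes = "te", contralateral = NULL) {
  structure(list(variant = "variance_only",
                 mediators = setdiff(phenotypes, c("te", "ptsdsx")),
                 phenotypes = phenotypes,
                 free_paths = character(0), contralateral = contralateral),
            class = "path_model")
}

# assemble the full paths list (a, b, c, a_rev, b_rev, c_rev) from a named
# vector of free path values, zeros elsewhere
paths_from_free <- function(model, values) {
  k <- length(model$mediators)
  get <- function(nm) if (nm %in% names(values)) values[[nm]] else 0
  list(
    a = vapply(model$mediators, function(m) get(paste0("a_", m)), numeric(1)),
    b = vapply(model$mediators, function(m) get(paste0("b_", m)), numeric(1)),
    a_rev = vapply(model$mediators, function(m) get(paste0("a_rev_", m)),
                   numeric(1)),
    b_rev = vapply(model$mediators, function(m) get(paste0("b_rev_", m)),
                   numeric(1)),
    c = get("c"), c_rev = get("c_rev")
  )
}

#' Model-implied mean and covariance for a cluster type
#'
#' Builds the implied per-pair (or per-person) moments of the
#' variance-components mediation SEM: with path matrix `B` and total-effect
#' matrix `G = (I - B)^-1`, the covariance between two cluster members is
#' `G (r Psi_A + f Psi_C + s Psi_S) G'` where `r` is the additive-genetic
#' relatedness (1 for MZ, 0.5 for DZ and full siblings, 0 for unrelated),
#' `f` indicates family sharing and `s` site sharing; the within-person
#' block adds `Psi_E`. Contralateral component correlations enter the `Psi`
#' off-diagonals.
#'
#' @param spec a [path_model()] or a [truth_record()] (which carries its own
#'   paths and components).
#' @param params for a `path_model`: list with `paths` (named free-path
#'   values), `components` (list of [variance_components()] per phenotype),
#'   optional `mu` and `contralateral` (with `rA`, `rC`, `rE` columns).
#'   Ignored for a `truth_record`.
#' @param pair_type `"MZ"`, `"DZ"`, `"SIB"`, `"unrelated_same_site"` or
#'   `"singleton"`.
#' @return List with `mean` and `cov` for the stacked cluster vector.
#' @export
build_implied_cov <- function(spec, params = NULL, pair_type = "MZ") {
  if (inherits(spec, "truth_record")) {
    phen <- spec$phenotypes
    B <- spec$B
    comps <- spec$components
    ctr <- spec$contralateral
    mu <- rep(0, length(phen))
  } else if (inherits(spec, "path_model")) {
    phen <- spec$phenotypes
    B <- build_path_matrix(paths_from_free(spec, unlist(params$paths)), phen)
    comps <- params$components
    ctr <- params$contralateral %||% spec$contralateral
    mu <- params$mu %||% rep(0, length(phen))
  } else stop_field("spec", "must be a path_model or truth_record")
  share <- switch(pair_type,
    MZ = c(r = 1, fam = 1, site = 1),
    DZ = c(r = 0.5, fam = 1, site = 1),
    SIB = c(r = 0.5, fam = 1, site = 1),
    unrelated_same_site = c(r = 0, fam = 0, site = 1),
    singleton = NULL,
    stop_field("pair_type", "unknown pair type")
  )
  G <- path_solve(B)
  PA <- psi_component(comps, "var_A", ctr)
  PC <- psi_component(comps, "var_C", ctr)
  PE <- psi_component(comps, "var_E", ctr)
  PS <- psi_component(comps, "var_S", ctr)
  within <- G %*% (PA + PC + PE + PS) %*% t(G)
  if (is.null(share)) {
    dimnames(within) <- list(phen, phen)
    return(list(mean = stats::setNames(mu, phen), cov = within))
  }
  cross <- G %*% (share[["r"]] * PA + share[["fam"]] * PC +
                    share[["site"]] * PS) %*% t(G)
  cov <- rbind(cbind(within, cross), cbind(t(cross), within))
  nm <- c(paste0(phen, "_1"), paste0(phen, "_2"))
  dimnames(cov) <- list(nm, nm)
  list(mean = stats::setNames(rep(mu, 2), nm), cov = cov)
}
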