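#' Variance components of a phenotype
#'
#' Container for the additive-genetic (A), shared-environmental (C),
#' unique-environmental (E) and data-collection-site (S) variance components
#' of a single standardized phenotype. Components are stored in variance
#' units; proportions are derived with [standardize_components()]. A negative
#' C (or S) estimate is representable and flagged on printing, since in twin
#' samples a negative shared-environment estimate can indicate non-additive
#' genetic variance.
#'
#' @param var_A,var_C,var_E,var_S component variances; `var_E` must be
#'   strictly positive (it absorbs measurement error), the others may take
#'   any finite value.
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(var_A, var_C, var_E, var_S = 0) {
  vals <- c(var_A = unname(var_A), var_C = unname(var_C),
            var_E = unname(var_E), var_S = unname(var_S))
  if (any(!is.finite(vals))) stop("variance components must be finite")
  if (var_E <= 0) stop("var_E must be strictly positive")
  structure(as.list(vals), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  v <- unlist(x)
  cat("Variance components (A, C, E, S):",
      paste(sprintf("%.4f", v), collapse = ", "), "\n")
  if (any(v[c("var_C", "var_S")] < 0))
    cat("note: negative shared component; may reflect non-additive genetic variance\n")
  invisible(x)
}

#' Standardize variance components to proportions
#'
#' Divides each component by the component sum, giving the proportion of
#' phenotypic variance attributable to A, C, E and S (the VA/VC/VE/VS
#' convention). When a parameter covariance matrix for
#' `(var_A, var_C, var_E, var_S)` is supplied, first-order delta-method 95%
#' confidence intervals are attached.
#'
#' @param vc a [variance_components()] object.
#' @param vcov optional 4x4 covariance matrix of the component estimates.
#' @param level confidence level for the intervals.
#' @return A data.frame with one row per component: proportion and,
#'   if `vcov` was given, lower/upper confidence bounds.
#' @export
standardize_components <- function(vc, vcov = NULL, level = 0.95) {
  v <- unlist(vc)
  tot <- sum(v)
  if (tot <= 0) stop("total variance must be positive")
  prop <- v / tot
  out <- data.frame(
    component = c("VA", "VC", "VE", "VS"),
    proportion = as.numeric(prop),
    stringsAsFactors = FALSE
  )
  if (!is.null(vcov)) {
    vcov <- symmetric_or_stop(as.matrix(vcov))
    # d(v_i / sum) / d v_j = (delta_ij * tot - v_i) / tot^2
    J <- (diag(4) * tot - matrix(v, 4, 4)) / tot^2
    se <- sqrt(pmax(0, diag(J %*% vcov %*% t(J))))
    z <- stats::qnorm(1 - (1 - level) / 2)
    out$lower <- out$proportion - z * se
    out$upper <- out$proportion + z * se
  }
  out
}

component_names <- c("var_A", "var_C", "var_E", "var_S")

# p x p within-person covariance of one latent component across phenotypes.
# `contralateral` is a data.frame(left, right, rA, rC, rE) of phenotype-name
# pairs whose A/C/E components are correlated (homologous left/right ROIs).
psi_component <- function(vc_list, component, contralateral = NULL) {
  p <- length(vc_list)
  v <- vapply(vc_list, function(z) z[[component]], numeric(1))
  psi <- diag(v, nrow = p)
  rownames(psi) <- colnames(psi) <- names(vc_list)
  rcol <- c(var_A = "rA", var_C = "rC", var_E = "rE")[component]
  if (!is.null(contralateral) && !is.na(rcol) && nrow(contralateral) > 0) {
    for (i in seq_len(nrow(contralateral))) {
      l <- contralateral$left[i]; r <- contralateral$right[i]
      rho <- contralateral[[rcol]][i]
      cov_lr <- rho * sqrt(abs(v[l]) * abs(v[r])) * sign(v[l]) * sign(v[r])
      psi[l, r] <- psi[r, l] <- cov_lr
    }
  }
  psi
}

# Path (regression) matrix B over phenotypes ordered (te, mediators..., ptsdsx):
# entry B[i, j] is the coefficient of phenotype j in the equation for i.
build_path_matrix <- function(paths, phenotypes) {
  p <- length(phenotypes)
  B <- matrix(0, p, p, dimnames = list(phenotypes, phenotypes))
  has_x <- "te" %in% phenotypes
  has_y <- "ptsdsx" %in% phenotypes
  med <- setdiff(phenotypes, c("te", "ptsdsx"))
  k <- length(med)
  if (k > 0 && has_x) B[med, "te"] <- paths$a %||% rep(0, k)
  if (k > 0 && has_y) {
    B["ptsdsx", med] <- paths$b %||% rep(0, k)
    B[med, "ptsdsx"] <- paths$a_rev %||% rep(0, k)
  }
  if (k > 0 && has_x) B["te", med] <- paths$b_rev %||% rep(0, k)
  if (has_x && has_y) {
    B["ptsdsx", "te"] <- paths$c %||% 0
    B["te", "ptsdsx"] <- paths$c_rev %||% 0
  }
  B
}

# total-effect matrix G = (I - B)^-1; errors on a structural feedback loop
path_solve <- function(B) {
  I <- diag(nrow(B))
  d <- det(I - B)
  if (!is.finite(d) || abs(d) < 1e-10)
    stop("(I - B) is singular: the structural paths form a feedback loop ",
         "with total effect 1 (check c, c_rev and reverse a/b paths)")
  out <- solve(I - B)
  dimnames(out) <- dimnames(B)
  out
}
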