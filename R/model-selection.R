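#' AIC from the degrees-of-freedom convention
#'
#' Computes Akaike's information criterion under the observed-statistics
#' convention `AIC = -2 ln L - 2 df`, where `df` is the number of observed
#' data points minus the number of estimated parameters. Vectorized and
#' exact.
#'
#' @param minus2ll twice the negative log-likelihood.
#' @param df degrees of freedom (non-negative).
#' @return `minus2ll - 2 * df`.
#' @export
aic_from_df <- function(minus2ll, df) {
  if (any(df < 0)) stop("df must be non-negative")
  minus2ll - 2 * df
}

#' Likelihood-ratio test between nested model fits
#'
#' Compares a nested (more constrained) fit against its base:
#' `chi-square = minus2ll_nested - minus2ll_base` with
#' `df = ep_base - ep_nested`, and the upper-tail chi-square probability.
#' Fits may be `sem_fit` objects or lists with `minus2ll`, `ep`, `df` and
#' `aic` fields.
#'
#' @param base the richer model fit.
#' @param nested the constrained fit (its free parameters must be a subset
#'   of the base's).
#' @param labels optional c(base, nested) model labels for the output row.
#' @param tol tolerance for a slightly negative chi-square due to optimizer
#'   noise (clipped to 0); beyond it the fits are not nested or one failed.
#' @return A one-row data.frame of class `comparison_row`: both models'
#'   `ep`, `minus2ll`, `df`, `aic`, plus `diff_ll`, `diff_df` and `p`.
#' @export
likelihood_ratio_test <- function(base, nested, labels = NULL, tol = 1e-4) {
  d_ll <- nested$minus2ll - base$minus2ll
  if (d_ll < -tol)
    stop(sprintf("nested fit beats its base by %.4g -2lnL units: models are not nested or a fit failed",
                 -d_ll))
  d_ll <- max(d_ll, 0)
  d_df <- base$ep - nested$ep
  if (d_df < 0) stop("nested model has more parameters than its base")
  p <- if (d_df == 0) as.numeric(d_ll <= tol) else
    stats::pchisq(d_ll, d_df, lower.tail = FALSE)
  out <- data.frame(
    base = labels[1] %||% "base", comparison = labels[2] %||% "nested",
    ep_base = base$ep, minus2ll_base = base$minus2ll, df_base = base$df,
    aic_base = base$aic,
    ep = nested$ep, minus2ll = nested$minus2ll, df = nested$df,
    aic = nested$aic,
    diff_ll = d_ll, diff_df = d_df, p = p,
    stringsAsFactors = FALSE
  )
  class(out) <- c("comparison_row", "data.frame")
  out
}

#' Effective number of independent tests
#'
#' Eigenvalue-based correction for correlated tests (Li-Ji construction):
#' `Meff = sum over eigenvalues of [I(lambda >= 1) + (lambda - floor(lambda))]`
#' on the eigenvalues of the correlation matrix of the tested variables.
#' `Meff` equals the number of variables for independent tests and 1 when
#' all are perfectly correlated.
#'
#' @param corr correlation matrix (symmetric, unit diagonal).
#' @param tol tolerance for symmetry and for slightly negative eigenvalues
#'   from finite samples.
#' @return Scalar `Meff` in `[1, p]`.
#' @export
effective_tests <- function(corr, tol = 1e-8) {
  corr <- symmetric_or_stop(as.matrix(corr), tol = max(tol, 1e-8))
  if (max(abs(diag(corr) - 1)) > 1e-6)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-6)) stop("matrix is not positive semi-definite")
  # round before floor(): an eigenvalue of 2 - 1e-15 must count as integer 2
  ev <- round(pmax(ev, 0), 10)
  m <- sum(ifelse(ev >= 1, 1, 0) + (ev - floor(ev)))
  min(max(m, 1), length(ev))
}

#' Select a model by parsimony among statistically equivalent fits
#'
#' Among the models not significantly worse than the best-fitting one at
#' `alpha_level` (by the likelihood-ratio p of their comparison rows), picks
#' the smallest AIC; ties are broken by the fewest estimated parameters.
#'
#' @param rows list of [likelihood_ratio_test()] rows sharing one base
#'   model, or a data.frame binding them.
#' @param alpha_level significance level for "significantly worse"
#'   (default 0.05).
#' @return The chosen model label.
#' @export
select_model <- function(rows, alpha_level = 0.05) {
  if (is.data.frame(rows)) rows <- split(rows, seq_len(nrow(rows)))
  if (!length(rows)) stop("no comparison rows supplied")
  base_label <- rows[[1]]$base
  cand <- data.frame(
    label = c(base_label, vapply(rows, function(r) r$comparison, character(1))),
    aic = c(rows[[1]]$aic_base, vapply(rows, function(r) r$aic, numeric(1))),
    ep = c(rows[[1]]$ep_base, vapply(rows, function(r) r$ep, numeric(1))),
    p = c(1, vapply(rows, function(r) r$p, numeric(1))),
    stringsAsFactors = FALSE
  )
  keep <- cand[cand$p >= alpha_level, , drop = FALSE]
  keep <- keep[order(keep$aic, keep$ep), , drop = FALSE]
  keep$label[1]
}
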