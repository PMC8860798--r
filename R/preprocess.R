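#' Mask ROI volumes failing MRI quality control
#'
#' Sets all ROI volume columns to missing for subjects whose QC score falls
#' strictly below the threshold (conventionally 600 usable frames). Rows are
#' retained: data from the subject's other measures stay in the table.
#'
#' @param table a cohort/analysis data.frame with a `qc_score` column.
#' @param roi_cols character vector of ROI column names.
#' @param threshold QC cutoff; scores `< threshold` are masked.
#' @return The table with masked ROI cells and an updated provenance log
#'   attribute.
#' @export
apply_qc_mask <- function(table, roi_cols, threshold = 600) {
  if (!"qc_score" %in% names(table)) stop("`qc_score` column is required")
  fail <- !is.na(table$qc_score) & table$qc_score < threshold
  for (col in roi_cols) table[[col]][fail] <- NA
  log_action(table, "qc_mask",
             sprintf("masked ROI cells for %d subjects with qc_score < %g",
                     sum(fail), threshold))
}

#' Remove covariate fixed effects and standardize
#'
#' Ordinary least-squares residuals of `y` on the covariate design
#' (categorical covariates one-hot coded), divided by the residual standard
#' deviation. The regression is fitted on complete cases; residuals are
#' computed for every row with complete covariates, and missing `y`
#' propagates to missing output.
#'
#' @param y numeric response vector (may contain NA).
#' @param covariates data.frame of covariates.
#' @return Standardized residual vector (mean 0, SD 1 on complete cases).
#' @export
residualize_standardize <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(y)) stop("covariate rows must match y")
  X <- stats::model.matrix(~., stats::model.frame(~., covariates,
                                                  na.action = stats::na.pass))
  cc <- stats::complete.cases(X) & !is.na(y)
  if (sum(cc) <= ncol(X)) stop("too few complete cases to residualize")
  fit <- stats::lm.fit(X[cc, , drop = FALSE], y[cc])
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient covariate design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  res <- rep(NA_real_, length(y))
  ok <- stats::complete.cases(X) & !is.na(y)
  res[ok] <- y[ok] - as.numeric(X[ok, , drop = FALSE] %*% fit$coefficients)
  res / stats::sd(res[cc])
}

#' Mask outliers beyond a standardized limit
#'
#' Datapoints surpassing the limit (strictly, `|z| > limit`) are coded
#' missing; the subject's other measures are retained. The column is assumed
#' already residualized and standardized.
#'
#' @param column standardized numeric vector.
#' @param limit SD limit (default 4).
#' @return The vector with outliers set to NA.
#' @export
mask_outliers <- function(column, limit = 4) {
  column[!is.na(column) & abs(column) > limit] <- NA
  column
}

#' Conditional missingness of the symptom score
#'
#' Subjects who endorsed no traumatic event cannot express post-traumatic
#' symptoms attributable to one; their symptom level is coded missing while
#' their traumatic-event and imaging data are retained.
#'
#' @param table data.frame with `te_count` and `ptsdsx_level` columns.
#' @return The table with the conditional mask applied.
#' @export
conditional_ptsdsx_missing <- function(table) {
  if (!all(c("te_count", "ptsdsx_level") %in% names(table)))
    stop("`te_count` and `ptsdsx_level` columns are required")
  zero <- !is.na(table$te_count) & table$te_count == 0
  table$ptsdsx_level[zero] <- NA
  log_action(table, "conditional_missing",
             sprintf("masked ptsdsx for %d subjects with zero endorsed TEs",
                     sum(zero)))
}

log_action <- function(table, stage, message) {
  log <- attr(table, "provenance") %||%
    data.frame(stage = character(), message = character(),
               stringsAsFactors = FALSE)
  attr(table, "provenance") <- rbind(log, data.frame(
    stage = stage, message = message, stringsAsFactors = FALSE))
  table
}

#' Full preprocessing pipeline for an analysis table
#'
#' Applies, in fixed order: conditional symptom missingness, the QC mask,
#' covariate residualization with standardization, and the 4 SD outlier
#' mask. Produces the analysis-ready standardized `te_score`, `ptsdsx_score`
#' and ROI residual columns. Row count never changes; only cell-level
#' missingness is introduced. Skewness and kurtosis of the processed scores
#' are recorded and a warning is raised when they approach the levels (2 and
#' 7) at which normal-theory maximum likelihood becomes unreliable.
#'
#' @param cohort a cohort data.frame containing item columns, covariates,
#'   ROI volumes, `qc_score` and total-volume columns.
#' @param roi_cols ROI volume column names (default: attribute or none).
#' @param qc_threshold,outlier_limit masking parameters.
#' @param inverse_normal if `TRUE`, apply a rank-based inverse-normal
#'   transform to the ordinal scores before residualization (sensitivity
#'   analysis); off by default.
#' @return An `analysis_table` data.frame with standardized score and ROI
#'   residual columns, plus a provenance log in `attr(, "provenance")`.
#' @export
preprocess_cohort <- function(cohort, roi_cols = character(),
                              qc_threshold = 600, outlier_limit = 4,
                              inverse_normal = FALSE) {
  te_cols <- grep("^te_item_", names(cohort), value = TRUE)
  px_cols <- grep("^ptsd_item_", names(cohort), value = TRUE)
  lv <- build_sum_score_levels(cohort[te_cols], cohort[px_cols])
  tab <- cbind(cohort, lv)
  tab <- conditional_ptsdsx_missing(tab)
  tab <- apply_qc_mask(tab, roi_cols, threshold = qc_threshold)

  maybe_int <- function(x) {
    if (!inverse_normal) return(x)
    r <- rank(x, na.last = "keep")
    stats::qnorm((r - 0.375) / (sum(!is.na(x)) + 0.25))
  }
  base_cov <- tab[, c("age", "sex", "ancestry")]
  tab$te_score <- residualize_standardize(maybe_int(tab$te_level), base_cov)
  tab$ptsdsx_score <- residualize_standardize(maybe_int(tab$ptsdsx_level),
                                              base_cov)
  for (col in roi_cols) {
    roi_cov <- cbind(base_cov, scanner = tab$scanner,
                     total_volume = tab$total_subcortical_volume)
    z <- residualize_standardize(tab[[col]], roi_cov)
    tab[[paste0(col, "_std")]] <- mask_outliers(z, limit = outlier_limit)
  }
  tab <- log_action(tab, "residualize_standardize",
                    "scores and ROI volumes residualized on covariates and standardized")
  tab <- log_action(tab, "outlier_mask",
                    sprintf("ROI residuals beyond %g SD coded missing", outlier_limit))

  for (sc in c("te_score", "ptsdsx_score")) {
    m <- moments_of(tab[[sc]])
    if (is.finite(m["skewness"]) &&
        (abs(m["skewness"]) > 2 || abs(m["kurtosis"]) > 7))
      warning(sprintf("%s skewness/kurtosis (%.2f/%.2f) approach levels problematic for ML",
                      sc, m["skewness"], m["kurtosis"]))
  }
  class(tab) <- c("analysis_table", "data.frame")
  tab
}

moments_of <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- stats::sd(x)
  c(skewness = mean((x - m)^3) / s^3,
    kurtosis = mean((x - m)^4) / s^4 - 3)
}
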