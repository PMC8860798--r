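#' Elastic-net objective
#'
#' The penalized least-squares loss minimized by the coordinate-descent
#' fitter:
#' `sum((y - b0 - X beta)^2) + lambda * sum((1 - alpha)/2 * beta_j^2 +
#' alpha * |beta_j|)`.
#' `alpha = 1` gives the LASSO (L1) penalty, `alpha = 0` ridge (L2), values
#' between mix the two. The intercept is never penalized. Note the penalty
#' applies to the raw residual sum of squares, so `lambda` is on the RSS
#' scale (a `glmnet` lambda corresponds to `lambda / (2 n)` here).
#'
#' @param beta coefficient vector.
#' @param intercept scalar intercept.
#' @param X predictor matrix.
#' @param y response vector.
#' @param lambda penalty magnitude (`>= 0`).
#' @param alpha L1/L2 mixing parameter in `[0, 1]`.
#' @return Scalar loss.
#' @export
en_objective <- function(beta, intercept, X, y, lambda, alpha) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  r <- y - intercept - as.numeric(X %*% beta)
  sum(r^2) + lambda * sum((1 - alpha) / 2 * beta^2 + alpha * abs(beta))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Elastic-net path by cyclic coordinate descent
#'
#' Fits the elastic-net coefficient path for one `alpha` over a decreasing
#' lambda sequence with warm starts. Columns are centered and scaled to
#' `x'x = n` internally; coefficients are reported on the original scale of
#' `X` and `y`. Each coordinate update is the exact minimizer of
#' [en_objective()] in that coordinate (soft-thresholding), so the objective
#' is non-increasing within every sweep.
#'
#' @param X predictor matrix (n x p).
#' @param y response vector.
#' @param alpha L1/L2 mixing parameter.
#' @param lambda optional decreasing positive lambda sequence; by default a
#'   geometric grid of `nlambda` points spanning three decades down from the
#'   smallest lambda that zeroes every coefficient.
#' @param nlambda,lambda_min_ratio automatic-grid controls.
#' @param tol convergence tolerance on the largest coefficient change per
#'   sweep (standardized scale).
#' @param max_sweeps sweep cap per lambda; exceeding it is an error.
#' @param standardize scale columns to `x'x = n` internally (default); with
#'   `FALSE` the penalty applies to the coefficients of `X` as supplied
#'   (columns are still centered for the intercept).
#' @return A list of class `en_path_slice`: `lambda`, `beta` (p x nlambda,
#'   original scale), `intercept` (per lambda), `alpha`, `df` (nonzero
#'   counts).
#' @export
fit_en_path <- function(X, y, alpha, lambda = NULL, nlambda = 100,
                        lambda_min_ratio = 1e-3, tol = 1e-9,
                        max_sweeps = 100000, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 observations")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  if (standardize) {
    xs <- sqrt(colSums(Xc^2) / n)
    xs[xs == 0] <- 1
  } else {
    xs <- rep(1, p)
  }
  Xs <- sweep(Xc, 2, xs, `/`)
  xtx <- colSums(Xs^2)                 # = n when standardized
  ym <- mean(y)
  yc <- y - ym

  if (is.null(lambda)) {
    lambda_max <- 2 * max(abs(crossprod(Xs, yc))) / max(alpha, 1e-3)
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    if (any(lambda < 0) ||
        (length(lambda) > 1 && is.unsorted(rev(lambda), strictly = TRUE)))
      stop("lambda must be a strictly decreasing non-negative sequence")
  }
  nlam <- length(lambda)
  betas <- matrix(0, p, nlam)
  beta <- rep(0, p)
  r <- yc
  for (l in seq_len(nlam)) {
    lam <- lambda[l]
    denom <- 2 * xtx + lam * (1 - alpha)
    thresh <- lam * alpha
    for (sweep_i in seq_len(max_sweeps)) {
      delta_max <- 0
      for (j in seq_len(p)) {
        bj <- beta[j]
        rho <- sum(Xs[, j] * r) + xtx[j] * bj
        bj_new <- soft_threshold(2 * rho, thresh) / denom[j]
        if (bj_new != bj) {
          r <- r - Xs[, j] * (bj_new - bj)
          delta_max <- max(delta_max, abs(bj_new - bj))
          beta[j] <- bj_new
        }
      }
      if (delta_max < tol) break
    }
    if (sweep_i == max_sweeps && delta_max >= tol)
      stop(sprintf("coordinate descent did not converge at lambda=%.4g (last max change %.3g)",
                   lam, delta_max))
    betas[, l] <- beta
  }
  beta_orig <- betas / xs
  intercept <- ym - as.numeric(crossprod(beta_orig, xm))
  rownames(beta_orig) <- colnames(X) %||% paste0("x", seq_len(p))
  structure(list(lambda = lambda, beta = beta_orig, intercept = intercept,
                 alpha = alpha, df = colSums(betas != 0)),
            class = "en_path_slice")
}

# KKT residuals of the en_objective at a fitted path point; returns the
# largest violation across coordinates (on the internal penalty scale)
en_kkt_violation <- function(X, y, fit, l, standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  xm <- colMeans(X); Xc <- sweep(X, 2, xm)
  if (standardize) {
    xs <- sqrt(colSums(Xc^2) / n); xs[xs == 0] <- 1
  } else {
    xs <- rep(1, ncol(X))
  }
  Xs <- sweep(Xc, 2, xs, `/`)
  yc <- y - mean(y)
  beta_std <- fit$beta[, l] * xs
  lam <- fit$lambda[l]; alpha <- fit$alpha
  r <- yc - as.numeric(Xs %*% beta_std)
  g <- -2 * as.numeric(crossprod(Xs, r)) + lam * (1 - alpha) * beta_std
  viol <- ifelse(beta_std != 0,
                 abs(g + lam * alpha * sign(beta_std)),
                 pmax(abs(g) - lam * alpha, 0))
  max(viol)
}

#' Cross-validation configuration for the elastic net
#'
#' @param alpha_grid mixing values to scan (default 0 to 1 in steps of
#'   0.05).
#' @param k_folds number of cross-validation folds (default 10).
#' @param nlambda points on the automatic lambda grid.
#' @param seed fold-assignment seed.
#' @return A list of class `en_config`.
#' @export
en_config <- function(alpha_grid = seq(0, 1, by = 0.05), k_folds = 10,
                      nlambda = 100, seed = 1L) {
  if (any(alpha_grid < 0 | alpha_grid > 1))
    stop_field("alpha_grid", "values must lie in [0, 1]")
  if (k_folds < 2) stop_field("k_folds", "must be at least 2")
  structure(list(alpha_grid = alpha_grid, k_folds = as.integer(k_folds),
                 nlambda = nlambda, seed = as.integer(seed)),
            class = "en_config")
}

#' K-fold cross-validation over the (alpha, lambda) grid
#'
#' For each mixing value `alpha`, fits the coordinate-descent path on each
#' training fold and scores held-out mean squared error, then locates
#' `lambda_min` (smallest mean CV-MSE) and `lambda_1se` (largest lambda
#' within one standard error of that minimum). Folds are assigned at the
#' family level when `family_id` is given, so twins and siblings never
#' straddle a train/validation split. The preferred `alpha` is the one whose
#' `[lambda_min, lambda_1se]` window has the smallest CV-MSE range (ties go
#' to the smaller minimum MSE).
#'
#' @param X predictor matrix.
#' @param y response vector; rows with missing response are dropped.
#' @param config an [en_config()].
#' @param family_id optional cluster labels for fold stratification.
#' @return An object of class `en_path`: per-alpha tables of `lambda`,
#'   `cv_mse`, `cv_mse_se`, `lambda_min`, `lambda_1se`, full-data
#'   coefficient paths, and the selected `alpha`.
#' @export
cross_validate <- function(X, y, config = en_config(), family_id = NULL) {
  X <- as.matrix(X)
  keep <- !is.na(y) & stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (!is.null(family_id)) family_id <- family_id[keep]
  n <- nrow(X)
  k <- config$k_folds
  if (k > n) stop("more folds than observations")
  set.seed(config$seed)
  if (is.null(family_id)) {
    fold <- sample(rep_len(seq_len(k), n))
  } else {
    fams <- unique(family_id)
    fam_fold <- sample(rep_len(seq_len(k), length(fams)))
    fold <- fam_fold[match(family_id, fams)]
  }

  per_alpha <- lapply(config$alpha_grid, function(alpha) {
    full <- fit_en_path(X, y, alpha = alpha, nlambda = config$nlambda)
    lam <- full$lambda
    mse_fold <- matrix(NA_real_, k, length(lam))
    for (f in seq_len(k)) {
      tr <- fold != f
      if (stats::var(y[tr]) == 0) {
        warning(sprintf("fold %d has constant training response; skipped", f))
        next
      }
      pf <- fit_en_path(X[tr, , drop = FALSE], y[tr], alpha = alpha,
                        lambda = lam)
      pred <- sweep(X[!tr, , drop = FALSE] %*% pf$beta, 2, -pf$intercept)
      mse_fold[f, ] <- colMeans((y[!tr] - pred)^2)
    }
    used <- colSums(!is.na(mse_fold)) > 0
    cv_mse <- colMeans(mse_fold, na.rm = TRUE)
    cv_se <- apply(mse_fold, 2, function(z) {
      z <- z[!is.na(z)]; stats::sd(z) / sqrt(length(z))
    })
    i_min <- which.min(cv_mse)
    ok_1se <- which(cv_mse <= cv_mse[i_min] + cv_se[i_min])
    i_1se <- min(ok_1se)      # largest lambda within one SE (grid decreasing)
    list(alpha = alpha, lambda = lam, cv_mse = cv_mse, cv_mse_se = cv_se,
         lambda_min = lam[i_min], lambda_1se = lam[i_1se],
         mse_range = cv_mse[i_1se] - cv_mse[i_min], mse_min = cv_mse[i_min],
         path = full)
  })
  ranges <- vapply(per_alpha, `[[`, numeric(1), "mse_range")
  mins <- vapply(per_alpha, `[[`, numeric(1), "mse_min")
  best <- order(ranges, mins)[1]
  structure(list(alphas = per_alpha, best_alpha = per_alpha[[best]]$alpha,
                 best = per_alpha[[best]], fold = fold),
            class = "en_path")
}

#' Select candidate mediators from a cross-validated path
#'
#' Predictors with a nonzero coefficient anywhere in the
#' `[lambda_min, lambda_1se]` window of the preferred alpha, ranked by
#' absolute coefficient at `lambda_min`. `max_mse_increase` narrows the
#' window to lambdas whose CV-MSE exceeds the minimum by at most that
#' amount (0 restricts selection to `lambda_min` exactly). An empty
#' selection is a valid result.
#'
#' @param path an `en_path` from [cross_validate()].
#' @param max_mse_increase optional cap on the CV-MSE increase over the
#'   minimum within the selection window.
#' @return Character vector of predictor names, ordered by decreasing
#'   importance, with the `lambda_min` coefficients as the
#'   `"coefficients"` attribute.
#' @export
select_mediators <- function(path, max_mse_increase = NULL) {
  b <- path$best
  lam <- b$lambda
  in_window <- lam >= b$lambda_min & lam <= b$lambda_1se
  if (!is.null(max_mse_increase))
    in_window <- in_window & (b$cv_mse <= b$mse_min + max_mse_increase)
  nz <- rowSums(b$path$beta[, in_window, drop = FALSE] != 0) > 0
  at_min <- b$path$beta[, which(lam == b$lambda_min)[1]]
  chosen <- names(which(nz))
  chosen <- chosen[order(-abs(at_min[chosen]))]
  structure(chosen, coefficients = at_min[chosen])
}
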