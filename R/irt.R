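#' Fit a single-factor full-information item factor model
#'
#' Marginal maximum-likelihood estimation of a unidimensional two-parameter
#' logistic (2PL) model for binary items, by an EM algorithm with fixed-point
#' Gauss-Hermite quadrature over the standard-normal latent trait. Each
#' item's endorsement probability is `plogis(a_i (theta - b_i))`; `b_i` is
#' the difficulty (the liability at which endorsement probability is exactly
#' one half) and `a_i` the discrimination. Standardized loadings are derived
#' from the discriminations under the conventional logistic/normal-ogive
#' scaling constant 1.702.
#'
#' Items with a single observed response category cannot be located on the
#' liability scale; they are excluded with a warning and recorded in the
#' `excluded` field.
#'
#' @param items binary matrix or data.frame (persons x items), entries 0/1
#'   or NA.
#' @param n_quadrature number of Gauss-Hermite nodes (default 49).
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   marginal log-likelihood.
#' @return An object of class `item_params`: a data.frame of per-item
#'   `discrimination`, `difficulty` and `loading`, with the marginal
#'   log-likelihood trajectory, link and scaling constant as attributes.
#' @export
fit_item_factor_model <- function(items, n_quadrature = 49,
                                  max_iter = 500, tol = 1e-6) {
  Y <- as.matrix(items)
  storage.mode(Y) <- "double"
  if (ncol(Y) < 2) stop("need at least 2 items")
  if (any(!(Y %in% c(0, 1, NA))))
    stop("item entries must be 0, 1 or missing")
  observed <- colSums(!is.na(Y))
  endorsed <- colSums(Y == 1, na.rm = TRUE)
  constant <- endorsed == 0 | endorsed == observed | observed == 0
  excluded <- colnames(Y) %||% paste0("item_", seq_len(ncol(Y)))
  excluded <- excluded[constant]
  if (any(constant)) {
    warning("excluding constant item(s): ", paste(excluded, collapse = ", "))
    Y <- Y[, !constant, drop = FALSE]
    if (ncol(Y) < 2) stop("fewer than 2 non-constant items remain")
  }
  n <- nrow(Y); k <- ncol(Y)
  q <- normal_quadrature(n_quadrature)
  theta <- q$nodes
  logw <- log(q$weights)

  Y0 <- Y; Y0[is.na(Y)] <- 0
  Y1 <- (1 - Y); Y1[is.na(Y)] <- 0
  Obs <- (!is.na(Y)) * 1

  a <- rep(1, k)
  b <- stats::qnorm(1 - pmin(pmax(colMeans(Y, na.rm = TRUE), 0.02), 0.98)) * 1.5
  ll_trace <- numeric(0)
  ll_old <- -Inf

  for (iter in seq_len(max_iter)) {
    P <- t(logistic_2pl(matrix(theta, length(theta), k, byrow = FALSE),
                        rep(a, each = length(theta)),
                        rep(b, each = length(theta))))
    # P is k x nodes; clamp away from 0/1 for stable logs
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    logP <- log(P); log1mP <- log(1 - P)
    # persons x nodes log joint
    L <- Y0 %*% logP + Y1 %*% log1mP
    L <- sweep(L, 2, logw, `+`)
    mx <- apply(L, 1, max)
    W <- exp(L - mx)
    denom <- rowSums(W)
    ll <- sum(mx + log(denom))
    post <- W / denom

    # expected endorsements and trial counts per item and node
    r_ik <- crossprod(Y0, post)          # k x nodes
    n_ik <- crossprod(Obs, post)
    for (j in seq_len(k)) {
      fit <- stats::glm.fit(x = cbind(1, theta),
                            y = r_ik[j, ] / pmax(n_ik[j, ], 1e-12),
                            weights = n_ik[j, ],
                            family = stats::quasibinomial())
      d <- fit$coefficients[1]; slope <- fit$coefficients[2]
      if (is.finite(slope) && slope > 1e-6) {
        a[j] <- slope
        b[j] <- -d / slope
      }
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1 && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (iter == max_iter && abs(ll - ll_old) >= tol)
    warning("EM reached max_iter before the log-likelihood tolerance")

  out <- data.frame(
    item = colnames(Y) %||% paste0("item_", seq_len(k)),
    discrimination = a,
    difficulty = b,
    loading = discrimination_to_loading(a),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("item_params", "data.frame"),
            logLik = ll, ll_trace = ll_trace, excluded = excluded,
            link = "logit", scaling = IRT_SCALING,
            n_quadrature = n_quadrature)
}

#' Difficulty location of an item
#'
#' Returns the liability value at which the item's 2PL response curve equals
#' exactly one half (its mean difficulty). With positive discrimination this
#' is the difficulty parameter itself.
#'
#' @param params an `item_params` data.frame (or any data.frame with
#'   `discrimination` and `difficulty` columns).
#' @param item item index or name.
#' @return The theta value with 50% endorsement probability.
#' @export
difficulty_location <- function(params, item = 1) {
  row <- if (is.character(item)) params[params$item == item, ] else params[item, ]
  if (nrow(row) != 1) stop("item not found")
  if (row$discrimination <= 0) stop("discrimination must be positive")
  row$difficulty
}

#' Proportion of item variance explained by the common factor
#'
#' Defined as the mean of the squared standardized loadings of the
#' single-factor solution.
#'
#' @param params an `item_params` data.frame with a `loading` column, or a
#'   numeric vector of standardized loadings.
#' @return A proportion in `[0, 1]`.
#' @export
variance_explained <- function(params) {
  lam <- if (is.numeric(params)) params else params$loading
  if (any(abs(lam) > 1)) stop("loadings must be standardized")
  mean(lam^2)
}

#' Ordinal sum-score level variables
#'
#' Collapses raw item counts into the ordinal level variables used for
#' modeling: traumatic-event counts map to 3 ordered levels and
#' PTSD-symptom counts to 4. The symptom count spans all diagnostic
#' criteria, so it includes the criterion-A (traumatic-event) items as well
#' as the remaining symptom items. Because PTSD diagnosis presupposes
#' exposure, the symptom level is coded missing for subjects endorsing no
#' traumatic event; those subjects are retained with their other data.
#' Counts are computed over non-missing items; a subject with all items
#' missing gets a missing level.
#'
#' @param te_items binary matrix of traumatic-event (criterion A) items.
#' @param ptsd_items binary matrix of the remaining PTSD-criterion items.
#' @param te_breaks counts opening each TE level: default `{0} -> 0`,
#'   `{1} -> 1`, `{>=2} -> 2`.
#' @param ptsd_breaks counts opening PTSD levels 2..4: default `{<=1} -> 1`,
#'   `{2} -> 2`, `{3} -> 3`, `{>=4} -> 4`.
#' @return data.frame with `te_count`, `ptsd_count`, `te_level` (0-2) and
#'   `ptsdsx_level` (1-4 or NA).
#' @export
build_sum_score_levels <- function(te_items, ptsd_items,
                                   te_breaks = c(1, 2),
                                   ptsd_breaks = c(2, 3, 4)) {
  te_items <- as.matrix(te_items); ptsd_items <- as.matrix(ptsd_items)
  count_of <- function(m) {
    cnt <- rowSums(m, na.rm = TRUE)
    cnt[rowSums(!is.na(m)) == 0] <- NA
    cnt
  }
  te_count <- count_of(te_items)
  ptsd_count <- count_of(cbind(te_items, ptsd_items))
  te_level <- findInterval(te_count, te_breaks)          # 0,1,2
  ptsdsx_level <- findInterval(ptsd_count, ptsd_breaks) + 1L  # 1..4
  ptsdsx_level[is.na(te_count) | te_count == 0] <- NA
  data.frame(te_count = te_count, ptsd_count = ptsd_count,
             te_level = te_level, ptsdsx_level = ptsdsx_level)
}
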