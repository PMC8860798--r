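# internal parameter map: packs means, free paths, per-phenotype variance
# components (var_E and var_S on the log scale: E must stay positive and the
# exact site-block likelihood exists only for non-negative site variance; A
# and C direct so negative shared components remain representable) and
# contralateral component correlations (atanh scale)
param_map <- function(model) {
  phen <- model$phenotypes
  comp_names <- as.vector(outer(c("var_A", "var_C", "log_var_E", "log_var_S"),
                                phen, function(a, b) paste(b, a, sep = ".")))
  ctr_names <- character(0)
  if (!is.null(model$contralateral)) {
    pr <- paste(model$contralateral$left, model$contralateral$right, sep = ":")
    ctr_names <- as.vector(outer(c("rA", "rC", "rE"), pr,
                                 function(a, b) paste(b, a, sep = ".")))
  }
  nm <- c(paste0("mu_", phen), model$free_paths, comp_names, ctr_names)
  list(names = nm, n = length(nm), phen = phen,
       i_mu = seq_along(phen),
       i_path = length(phen) + seq_along(model$free_paths),
       i_comp = length(phen) + length(model$free_paths) +
         seq_along(comp_names),
       i_ctr = length(phen) + length(model$free_paths) + length(comp_names) +
         seq_along(ctr_names))
}

unpack_params <- function(model, map, par) {
  phen <- map$phen
  mu <- par[map$i_mu]
  paths <- stats::setNames(par[map$i_path], model$free_paths)
  comp <- matrix(par[map$i_comp], nrow = 4)
  components <- lapply(seq_along(phen), function(i)
    variance_components(comp[1, i], comp[2, i], exp(comp[3, i]),
                        exp(comp[4, i])))
  names(components) <- phen
  ctr <- NULL
  if (length(map$i_ctr)) {
    cv <- tanh(par[map$i_ctr])
    cm <- matrix(cv, nrow = 3)
    ctr <- model$contralateral
    ctr$rA <- cm[1, ]; ctr$rC <- cm[2, ]; ctr$rE <- cm[3, ]
  }
  list(mu = mu, paths = paths, components = components, contralateral = ctr)
}

# natural-scale view of the internal vector (var_E exponentiated,
# correlations tanh'd); used to report estimates and delta-method SEs
natural_params <- function(map, par) {
  out <- par
  names(out) <- map$names
  exp_idx <- map$i_comp[grepl("log_var_[ES]", map$names[map$i_comp])]
  out[exp_idx] <- exp(out[exp_idx])
  names(out) <- sub("log_var_E", "var_E", names(out))
  names(out) <- sub("log_var_S", "var_S", names(out))
  if (length(map$i_ctr)) out[map$i_ctr] <- tanh(out[map$i_ctr])
  out
}

# moment-based starting values: per-phenotype means/variances, twin-moment
# estimates of A and C (Falconer-style), regression starts for the paths,
# and residual scaling of the component split by the structural R^2
default_start <- function(model, map, data) {
  phen <- map$phen
  p <- length(phen)
  sums <- numeric(p); sqs <- numeric(p); ns <- numeric(p)
  # cross-twin products per phenotype, split by relatedness
  cx <- list(`1` = numeric(p), `0.5` = numeric(p))
  cn <- list(`1` = numeric(p), `0.5` = numeric(p))
  # pooled within-person cross-products over complete rows
  Cpp <- matrix(0, p, p); n_pp <- 0; msum <- numeric(p)
  for (g in data$groups) {
    for (j in seq_len(ncol(g$Y))) {
      ph <- g$phen[j]
      v <- g$Y[, j]
      sums[ph] <- sums[ph] + sum(v); sqs[ph] <- sqs[ph] + sum(v^2)
      ns[ph] <- ns[ph] + length(v)
    }
    if (g$m == 2) {
      key <- as.character(g$r)
      if (!is.null(cx[[key]])) {
        for (ph in seq_len(p)) {
          j1 <- which(g$obs <= p & g$phen == ph)
          j2 <- which(g$obs > p & g$phen == ph)
          if (length(j1) == 1 && length(j2) == 1) {
            cx[[key]][ph] <- cx[[key]][ph] + sum(g$Y[, j1] * g$Y[, j2])
            cn[[key]][ph] <- cn[[key]][ph] + nrow(g$Y)
          }
        }
      }
    }
    for (member in seq_len(g$m)) {
      jm <- which(g$obs > (member - 1) * p & g$obs <= member * p)
      if (length(jm) == p) {
        Ym <- g$Y[, jm[order(g$phen[jm])], drop = FALSE]
        Cpp <- Cpp + crossprod(Ym); msum <- msum + colSums(Ym)
        n_pp <- n_pp + nrow(Ym)
      }
    }
  }
  m <- sums / pmax(ns, 1)
  v <- pmax(sqs / pmax(ns, 1) - m^2, 0.05)
  cov_mz <- ifelse(cn[["1"]] > 1, cx[["1"]] / cn[["1"]] - m^2, 0.4 * v)
  cov_dz <- ifelse(cn[["0.5"]] > 1, cx[["0.5"]] / cn[["0.5"]] - m^2, 0.25 * v)
  A0 <- pmin(pmax(2 * (cov_mz - cov_dz), 0.05 * v), 0.85 * v)
  C0 <- pmin(pmax(2 * cov_dz - cov_mz, 0.02 * v), 0.85 * v)
  S0 <- pmax(0.01 * v, 1e-4)
  E0 <- pmax(v - A0 - C0 - S0, 0.05 * v)

  par <- numeric(map$n)
  par[map$i_mu] <- m
  paths0 <- stats::setNames(rep(0, length(model$free_paths)),
                            model$free_paths)
  resid_frac <- rep(1, p)
  if (n_pp > p + 1 && length(model$free_paths)) {
    Cw <- Cpp / n_pp - tcrossprod(msum / n_pp)
    dimnames(Cw) <- list(phen, phen)
    med <- model$mediators
    reg_start <- function(x_name, med_names, y_name) {
      # a_j from simple regressions M_j ~ X; b, c from Y ~ X + M
      for (mm in med_names) {
        nm <- paste0(ifelse(x_name == "te", "a_", "a_rev_"), mm)
        if (nm %in% names(paths0))
          paths0[[nm]] <<- Cw[x_name, mm] / Cw[x_name, x_name]
      }
      pred <- c(x_name, med_names)
      bc <- tryCatch(solve(Cw[pred, pred, drop = FALSE], Cw[pred, y_name]),
                     error = function(e) NULL)
      if (!is.null(bc)) {
        cn2 <- if (x_name == "te") "c" else "c_rev"
        if (cn2 %in% names(paths0)) paths0[[cn2]] <<- bc[[x_name]]
        for (mm in med_names) {
          nm <- paste0(ifelse(x_name == "te", "b_", "b_rev_"), mm)
          if (nm %in% names(paths0)) paths0[[nm]] <<- bc[[mm]]
        }
        resid_frac[match(y_name, phen)] <<-
          max(0.1, 1 - sum(bc * Cw[pred, y_name]) / Cw[y_name, y_name])
        for (mm in med_names) {
          r2 <- Cw[x_name, mm]^2 / (Cw[x_name, x_name] * Cw[mm, mm])
          resid_frac[match(mm, phen)] <<- max(0.1, 1 - r2)
        }
      }
    }
    if (all(c("te", "ptsdsx") %in% phen)) {
      if (any(grepl("^(a_(?!rev)|b_(?!rev)|c$)", names(paths0), perl = TRUE)))
        reg_start("te", med, "ptsdsx")
      if (model$variant == "uniDir_reversed")
        reg_start("ptsdsx", med, "te")
      if (model$variant %in% c("biDir", "saturated"))
        paths0["c_rev"] <- 0
    }
  }
  par[map$i_path] <- paths0
  comp <- rbind(A0 * resid_frac, C0 * resid_frac,
                log(E0 * resid_frac), log(S0 * resid_frac))
  par[map$i_comp] <- as.vector(comp)
  if (length(map$i_ctr)) par[map$i_ctr] <- atanh(0.2)
  par
}

#' Fit the multilevel variance-components mediation SEM
#'
#' Minimizes the FIML `-2 ln L` ([fiml_neg2ll()]) by quasi-Newton search
#' from `n_starts` jittered starting points, keeping the best converged
#' solution. Unique-environment and site variances are log-parameterized
#' (E includes measurement error and must stay positive, and the site-block
#' likelihood requires non-negative site variance); A and C components are
#' unconstrained, so negative shared-environment estimates remain visible.
#'
#' @param model a [path_model()].
#' @param data a [fiml_data()] object, or a data.frame together with
#'   `columns`.
#' @param columns phenotype-to-column mapping passed to [fiml_data()] when
#'   `data` is a data.frame.
#' @param n_starts number of jittered optimizer starts (default 5).
#' @param seed seed for the start jitter.
#' @param ci `"delta"` (default) for delta-method 95% intervals from the
#'   numerical Hessian, `"none"` to skip interval computation (faster for
#'   simulation studies).
#' @param start optional internal-scale start vector (advanced use).
#' @return An object of class `sem_fit`: natural-scale `estimates`, the
#'   `minus2ll`, estimated-parameter count `ep`, degrees of freedom
#'   `df = n_obs_stats - ep`, `aic = minus2ll - 2 df`, convergence
#'   diagnostics, and (with `ci = "delta"`) a CI table and covariance
#'   matrix.
#' @export
fit_ml <- function(model, data, columns = NULL, n_starts = 5, seed = 1L,
                   ci = c("delta", "none"), start = NULL) {
  ci <- match.arg(ci)
  if (!inherits(data, "fiml_data")) {
    if (is.null(columns)) stop("supply `columns` when `data` is a data.frame")
    data <- fiml_data(data, columns)
  }
  if (!identical(data$phenotypes, model$phenotypes))
    stop("data phenotypes do not match the model (order matters)")
  map <- param_map(model)
  objective <- function(par) {
    tryCatch({
      pr <- unpack_params(model, map, par)
      B <- build_path_matrix(paths_from_free(model, pr$paths), map$phen)
      d <- det(diag(length(map$phen)) - B)
      if (!is.finite(d) || abs(d) < 1e-8) return(1e12)
      G <- solve(diag(length(map$phen)) - B)
      PA <- psi_component(pr$components, "var_A", pr$contralateral)
      PC <- psi_component(pr$components, "var_C", pr$contralateral)
      PE <- psi_component(pr$components, "var_E", pr$contralateral)
      PS <- psi_component(pr$components, "var_S", pr$contralateral)
      out <- fiml_core(data, G, PA, PC, PE, G %*% PS %*% t(G), pr$mu)
      if (!out$ok) return(1e12)
      out$value
    }, error = function(e) 1e12)
  }
  base_start <- start %||% default_start(model, map, data)
  set.seed(seed)
  starts <- list(base_start)
  if (n_starts > 1)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- base_start + stats::rnorm(map$n, 0, 0.1)

  lower <- rep(-Inf, map$n)
  lower[map$i_comp[grepl("log_var_[ES]", map$names[map$i_comp])]] <- -20
  fits <- lapply(starts, function(s)
    tryCatch(stats::nlminb(s, objective, lower = lower,
                           control = list(iter.max = 1000, eval.max = 4000,
                                          rel.tol = 1e-10)),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all optimizer starts failed")
  vals <- vapply(fits, function(f) if (is.null(f)) Inf else f$objective,
                 numeric(1))
  best <- fits[[which.min(vals)]]
  if (best$objective >= 1e12)
    stop("no start reached a positive-definite solution")
  # polish non-clean exits (singular/false convergence) from the best point
  if (best$convergence != 0) {
    polish <- stats::nlminb(best$par, objective, lower = lower,
                            control = list(iter.max = 500, eval.max = 2000,
                                           rel.tol = 1e-12))
    if (polish$objective <= best$objective) best <- polish
  }

  par <- best$par
  grad <- numDeriv::grad(objective, par, method = "simple")
  est <- natural_params(map, par)
  pr <- unpack_params(model, map, par)
  ep <- map$n
  df <- data$n_obs_total - ep
  m2ll <- best$objective
  out <- list(
    model = model, estimates = est, params = pr,
    minus2ll = m2ll, ep = ep, n_obs_stats = data$n_obs_total, df = df,
    aic = m2ll - 2 * df,
    convergence = best$convergence, message = best$message,
    gradient_norm = max(abs(grad)),
    internal_par = par, map = map
  )
  if (ci == "delta") {
    H <- tryCatch(numDeriv::hessian(objective, par,
                                    method.args = list(r = 2)),
                  error = function(e) NULL)
    vc <- if (!is.null(H))
      tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(vc)) {
      J <- diag(map$n)
      exp_idx <- which(grepl("log_var_[ES]", map$names))
      diag(J)[exp_idx] <- exp(par[exp_idx])
      if (length(map$i_ctr))
        diag(J)[map$i_ctr] <- 1 - tanh(par[map$i_ctr])^2
      vc_nat <- J %*% vc %*% t(J)
      dimnames(vc_nat) <- list(names(est), names(est))
      se <- sqrt(pmax(0, diag(vc_nat)))
      z <- stats::qnorm(0.975)
      out$vcov <- vc_nat
      out$ci <- data.frame(parameter = names(est), estimate = est, se = se,
                           lower = est - z * se, upper = est + z * se,
                           row.names = NULL)
    } else {
      out$ci_failure <- "Hessian not invertible; no delta-method intervals"
    }
  }
  class(out) <- "sem_fit"
  out
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("Variance-components mediation SEM (%s)\n", x$model$variant))
  cat(sprintf("  -2lnL = %.3f  ep = %d  df = %d  AIC = %.3f\n",
              x$minus2ll, x$ep, x$df, x$aic))
  cat(sprintf("  convergence: %d (%s); max |gradient| = %.2g\n",
              x$convergence, x$message %||% "", x$gradient_norm))
  paths <- x$estimates[x$model$free_paths]
  if (length(paths))
    cat("  paths:", paste(sprintf("%s=%.4f", names(paths), paths),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Re-optimizes all other parameters on a grid of fixed values of the
#' target parameter and locates where `-2 ln L` rises by the chi-square(1)
#' cutoff (3.841 for 95%). Falls back to the delta-method bound, flagged in
#' the result, if the profile search fails on a side.
#'
#' @param fit a [fit_ml()] result (fitted with `ci = "delta"` so an SE is
#'   available for bracketing).
#' @param parameter internal parameter name (see `fit$map$names`).
#' @param level confidence level.
#' @param data the [fiml_data()] used for the fit.
#' @return data.frame with lower/upper bounds and the method used per side.
#' @export
profile_ci <- function(fit, parameter, data, level = 0.95) {
  map <- fit$map
  i <- match(parameter, map$names)
  if (is.na(i)) stop("unknown parameter: ", parameter)
  model <- fit$model
  cut <- fit$minus2ll + stats::qchisq(level, 1)
  obj_fixed <- function(val) {
    objective <- function(par_rest) {
      par <- numeric(map$n)
      par[-i] <- par_rest; par[i] <- val
      pr <- unpack_params(model, map, par)
      fiml_neg2ll(model, pr, data)
    }
    stats::nlminb(fit$internal_par[-i], objective,
                  control = list(iter.max = 500))$objective
  }
  se <- if (!is.null(fit$vcov)) sqrt(fit$vcov[i, i]) else
    abs(fit$internal_par[i]) * 0.25 + 0.05
  est <- fit$internal_par[i]
  bound <- function(direction) {
    f <- function(val) obj_fixed(val) - cut
    lo <- est; hi <- est + direction * 6 * se
    fl <- f(hi); tries <- 0
    while (fl < 0 && tries < 4) { hi <- hi + direction * 4 * se; fl <- f(hi); tries <- tries + 1 }
    if (fl < 0) return(c(NA, NA))
    r <- tryCatch(stats::uniroot(f, sort(c(lo, hi)), tol = 1e-5),
                  error = function(e) NULL)
    if (is.null(r)) c(NA, NA) else c(r$root, 0)
  }
  up <- bound(1); dn <- bound(-1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  lower <- if (is.na(dn[1])) est - z * se else dn[1]
  upper <- if (is.na(up[1])) est + z * se else up[1]
  data.frame(parameter = parameter, estimate = est,
             lower = lower, upper = upper,
             method_lower = if (is.na(dn[1])) "delta" else "profile",
             method_upper = if (is.na(up[1])) "delta" else "profile",
             row.names = NULL)
}

#' Indirect (mediated) effect a x b
#'
#' The indirect effect of the exposure on the outcome through one mediator
#' is the product of its a-path (exposure to mediator) and b-path (mediator
#' to outcome). When the 2x2 covariance of `(a, b)` is supplied, a
#' first-order delta-method 95% interval is attached
#' (`var = b^2 Va + a^2 Vb + 2 a b Cab`).
#'
#' @param a,b path coefficients, or a single `sem_fit` as `a` together with
#'   a mediator name in `b`.
#' @param vcov optional 2x2 covariance matrix of `(a, b)`.
#' @param level confidence level.
#' @return List with `estimate` and, when a covariance is available,
#'   `lower`, `upper` and `method`.
#' @export
indirect_effect <- function(a, b, vcov = NULL, level = 0.95) {
  if (inherits(a, "sem_fit")) {
    fit <- a; med <- b
    an <- paste0("a_", med); bn <- paste0("b_", med)
    if (!all(c(an, bn) %in% names(fit$estimates)))
      stop("mediator paths not found in fit: ", med)
    vcov <- if (!is.null(fit$vcov)) fit$vcov[c(an, bn), c(an, bn)]
    a <- fit$estimates[[an]]; b <- fit$estimates[[bn]]
  }
  est <- a * b
  out <- list(estimate = est)
  if (!is.null(vcov)) {
    v <- b^2 * vcov[1, 1] + a^2 * vcov[2, 2] + 2 * a * b * vcov[1, 2]
    z <- stats::qnorm(1 - (1 - level) / 2)
    out$lower <- est - z * sqrt(max(v, 0))
    out$upper <- est + z * sqrt(max(v, 0))
    out$method <- "delta"
  }
  out
}

#' Saturated-model twin correlations
#'
#' Cross-twin within-trait, cross-twin cross-trait and within-person
#' cross-trait correlations for the MZ and DZ groups, with Fisher-z 95%
#' confidence intervals. With complete same-sex pairs the saturated-model
#' maximum-likelihood estimates coincide with the per-group sample moments
#' used here. The combined matrix places MZ correlations below the diagonal
#' and DZ correlations above it.
#'
#' @param data data.frame with `family_id`, `relation` and the score
#'   columns.
#' @param columns named character vector mapping phenotype names to score
#'   columns.
#' @param level confidence level for the intervals.
#' @return List with per-group correlation/CI matrices (`mz`, `dz`), pair
#'   counts and the `combined` MZ-below/DZ-above matrix.
#' @export
twin_saturated_correlations <- function(data, columns, level = 0.95) {
  data <- as.data.frame(data)
  group_wide <- function(rel) {
    d <- data[data$relation == rel, , drop = FALSE]
    sp <- split(seq_len(nrow(d)), d$family_id)
    sp <- sp[vapply(sp, length, integer(1)) == 2]
    if (!length(sp)) return(NULL)
    rows <- do.call(rbind, lapply(sp, function(ix) c(ix[1], ix[2])))
    w <- cbind(as.matrix(d[rows[, 1], columns, drop = FALSE]),
               as.matrix(d[rows[, 2], columns, drop = FALSE]))
    colnames(w) <- c(paste0(names(columns), "_T1"), paste0(names(columns), "_T2"))
    w
  }
  one_group <- function(rel) {
    w <- group_wide(rel)
    if (is.null(w) || nrow(w) < 3) {
      warning(sprintf("fewer than 3 complete %s pairs; correlations missing", rel))
      return(NULL)
    }
    R <- stats::cor(w, use = "pairwise.complete.obs")
    n <- nrow(w)
    z <- stats::qnorm(1 - (1 - level) / 2)
    fz <- atanh(pmin(pmax(R, -0.999999), 0.999999))
    se <- 1 / sqrt(n - 3)
    list(cor = R, lower = tanh(fz - z * se), upper = tanh(fz + z * se), n = n)
  }
  mz <- one_group("MZ"); dz <- one_group("DZ")
  combined <- NULL
  if (!is.null(mz) && !is.null(dz)) {
    combined <- mz$cor
    combined[upper.tri(combined)] <- dz$cor[upper.tri(dz$cor)]
    diag(combined) <- 1
  }
  list(mz = mz, dz = dz, combined = combined)
}

#' Penalized-path SEM fit
#'
#' Adds the elastic-net penalty of [en_objective()] on the mediator path
#' coefficients (the a- and b-paths, in either direction; never the direct
#' paths) to the FIML `-2 ln L`, and minimizes with the same quasi-Newton
#' search. Large `lambda` drives the mediator paths toward zero while the
#' direct path is retained; `lambda = 0` reduces to [fit_ml()].
#'
#' @param model a [path_model()].
#' @param data a [fiml_data()] object.
#' @param lambda,alpha penalty magnitude (on the `-2 ln L` scale) and
#'   L1/L2 mixing parameter, typically taken from [cross_validate()].
#' @param ... passed to [fit_ml()] (`n_starts`, `seed`, ...).
#' @return A `sem_fit`; `minus2ll` and `aic` are reported at the
#'   unpenalized likelihood of the shrunken solution, with the penalty
#'   recorded in `penalty`.
#' @export
penalized_path_fit <- function(model, data, lambda, alpha = 1, ...) {
  if (lambda < 0) stop("lambda must be non-negative")
  med_paths <- grep("^(a|b|a_rev|b_rev)_", model$free_paths, value = TRUE)
  map <- param_map(model)
  pen_idx <- map$i_path[model$free_paths %in% med_paths]
  fit <- fit_ml_penalized(model, data, lambda, alpha, pen_idx, ...)
  fit
}

fit_ml_penalized <- function(model, data, lambda, alpha, pen_idx,
                             n_starts = 3, seed = 1L, ci = "none") {
  map <- param_map(model)
  penalty <- function(par) {
    b <- par[pen_idx]
    lambda * sum((1 - alpha) / 2 * b^2 + alpha * abs(b))
  }
  objective <- function(par) {
    tryCatch({
      pr <- unpack_params(model, map, par)
      as.numeric(fiml_neg2ll(model, pr, data)) + penalty(par)
    }, error = function(e) 1e12)
  }
  base_start <- default_start(model, map, data)
  set.seed(seed)
  starts <- list(base_start)
  if (n_starts > 1)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- base_start + stats::rnorm(map$n, 0, 0.1)
  fits <- lapply(starts, function(s)
    tryCatch(stats::nlminb(s, objective,
                           control = list(iter.max = 1000, eval.max = 4000,
                                          rel.tol = 1e-12)),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all optimizer starts failed")
  vals <- vapply(fits, function(f) if (is.null(f)) Inf else f$objective,
                 numeric(1))
  best <- fits[[which.min(vals)]]
  par <- best$par
  pr <- unpack_params(model, map, par)
  m2ll <- fiml_neg2ll(model, pr, data)
  ep <- map$n
  df <- data$n_obs_total - ep
  structure(list(
    model = model, estimates = natural_params(map, par), params = pr,
    minus2ll = as.numeric(m2ll), ep = ep, n_obs_stats = data$n_obs_total,
    df = df, aic = as.numeric(m2ll) - 2 * df,
    penalty = penalty(par), lambda = lambda, alpha = alpha,
    convergence = best$convergence, message = best$message,
    gradient_norm = NA_real_, internal_par = par, map = map
  ), class = "sem_fit")
}
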