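#' Prepare clustered score data for FIML evaluation
#'
#' Groups the analysis table into site-level blocks of families, indexes the
#' observed (non-missing) entries of every family, and pools families with
#' identical (relatedness, missingness-pattern) keys so the likelihood can
#' be evaluated pattern-wise with one Cholesky per pattern instead of one
#' per family.
#'
#' @param data data.frame with `family_id`, `site_id` and `relation`
#'   columns.
#' @param columns named character vector mapping phenotype names (in model
#'   order: `te`, mediators..., `ptsdsx`) to score columns of `data`.
#' @return An object of class `fiml_data`.
#' @export
fiml_data <- function(data, columns) {
  missing_cols <- setdiff(c(columns, "family_id", "site_id", "relation"),
                          names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  Y <- as.matrix(as.data.frame(data)[, columns, drop = FALSE])
  colnames(Y) <- names(columns) %||% columns
  p <- ncol(Y)
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  fam <- as.character(data$family_id[keep])
  site <- as.character(data$site_id[keep])
  rel <- as.character(data$relation[keep])
  r_of <- c(MZ = 1, DZ = 0.5, SIB = 0.5, SINGLETON = 0)
  if (any(!rel %in% names(r_of)))
    stop("relation must be one of MZ, DZ, SIB, SINGLETON")

  ord <- order(site, fam)
  Y <- Y[ord, , drop = FALSE]; fam <- fam[ord]; site <- site[ord]
  rel <- rel[ord]
  fam_idx <- split(seq_along(fam), factor(fam, levels = unique(fam)))

  groups <- list(); gkey <- character()
  for (rows in fam_idx) {
    m <- length(rows)
    if (m > 2) stop("families larger than two scored members are not supported")
    obs_mask <- !is.na(t(Y[rows, , drop = FALSE]))  # p x m, phenotype-fast
    obs <- which(as.vector(obs_mask))               # positions in 1..m*p
    if (!length(obs)) next
    r <- r_of[[rel[rows[1]]]]
    key <- paste(site[rows[1]], r, m, paste(obs, collapse = ","), sep = "|")
    vals <- as.vector(t(Y[rows, , drop = FALSE]))[obs]
    gi <- match(key, gkey)
    if (is.na(gi)) {
      gkey <- c(gkey, key)
      groups[[length(groups) + 1]] <- list(
        site = site[rows[1]], r = r, m = m, obs = obs,
        phen = ((obs - 1L) %% p) + 1L, vals = list(vals))
    } else {
      groups[[gi]]$vals[[length(groups[[gi]]$vals) + 1]] <- vals
    }
  }
  groups <- lapply(groups, function(g) {
    g$Y <- do.call(rbind, g$vals)
    g$vals <- NULL
    g$Z <- matrix(0, length(g$obs), p)
    g$Z[cbind(seq_along(g$obs), g$phen)] <- 1
    g$colsum <- colSums(g$Y)
    g$CP <- crossprod(g$Y)     # sufficient statistics for the Gaussian block
    g$n <- nrow(g$Y)
    g
  })
  n_obs_total <- sum(vapply(groups, function(g) nrow(g$Y) * ncol(g$Y),
                            numeric(1)))
  site_of <- vapply(groups, `[[`, character(1), "site")
  site_groups <- split(seq_along(groups), factor(site_of, unique(site_of)))
  # pattern key ignoring the site, for the per-eval Cholesky cache
  pattern_key <- vapply(groups, function(g)
    paste(g$r, g$m, paste(g$obs, collapse = ","), sep = "|"), character(1))
  structure(list(groups = groups, p = p, phenotypes = colnames(Y),
                 sites = unique(site), n_persons = nrow(Y),
                 n_obs_total = n_obs_total, site_groups = site_groups,
                 pattern_id = match(pattern_key, unique(pattern_key))),
            class = "fiml_data")
}

#' @export
print.fiml_data <- function(x, ...) {
  cat(sprintf("FIML data: %d persons, %d phenotypes, %d sites, %d pattern groups, %d observed datapoints\n",
              x$n_persons, x$p, length(x$sites), length(x$groups),
              x$n_obs_total))
  invisible(x)
}

# -2 log-likelihood core. Site covariance = blockdiag(family blocks without
# the site component) + shared site term Z W Z' with W = G Psi_S G'; the
# shared term is absorbed with the Woodbury identity and the matrix
# determinant lemma, so each site costs one p x p solve on top of one small
# Cholesky per missingness pattern.
fiml_core <- function(prep, G, PA, PC, PE, W, mu) {
  p <- prep$p
  V <- G %*% (PA + PC + PE) %*% t(G)
  GA <- G %*% PA %*% t(G); GC <- G %*% PC %*% t(G)
  mu2 <- c(mu, mu)
  Ip <- diag(p)

  # one Cholesky per distinct (relatedness, size, pattern) per evaluation
  n_pat <- max(prep$pattern_id)
  blocks <- vector("list", n_pat)
  block_of <- function(g, id) {
    hit <- blocks[[id]]
    if (!is.null(hit)) return(hit)
    S_full <- if (g$m == 1) V else {
      cross <- g$r * GA + GC
      rbind(cbind(V, cross), cbind(cross, V))
    }
    Sk <- S_full[g$obs, g$obs, drop = FALSE]
    ch <- tryCatch(chol(Sk), error = function(e) NULL)
    out <- if (is.null(ch)) NULL else {
      Sinv <- chol2inv(ch)
      list(Sinv = Sinv, logdet = 2 * sum(log(diag(ch))),
           SinvZ = Sinv %*% g$Z, ZtSinvZ = crossprod(g$Z, Sinv %*% g$Z))
    }
    blocks[[id]] <<- out
    out
  }

  total <- 0
  for (gi_set in prep$site_groups) {
    M <- matrix(0, p, p); u <- numeric(p)
    q <- 0; ld <- 0; nobs <- 0
    for (gi in gi_set) {
      g <- prep$groups[[gi]]
      blk <- block_of(g, prep$pattern_id[gi])
      if (is.null(blk)) return(list(value = NA_real_, ok = FALSE))
      nk <- g$n
      mu_g <- mu2[g$obs]
      # quadratic form from the sufficient statistics:
      # sum_f (y_f - mu)' Sinv (y_f - mu)
      a1 <- blk$Sinv %*% mu_g
      q <- q + sum(blk$Sinv * g$CP) - 2 * sum(a1 * g$colsum) +
        nk * sum(a1 * mu_g)
      u <- u + as.numeric(crossprod(blk$SinvZ, g$colsum - nk * mu_g))
      M <- M + nk * blk$ZtSinvZ
      ld <- ld + nk * blk$logdet
      nobs <- nobs + nk * length(g$obs)
    }
    # site covariance D + Z W Z' is positive definite iff I + U W U' is,
    # with M = U'U; its log-determinant equals log det(I + M W)
    U <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(U)) {
      # singular M (a phenotype unobserved at this site): eigenvalue route
      ev <- Re(eigen(M %*% W, only.values = TRUE)$values)
      if (any(ev <= -1 + 1e-10)) return(list(value = NA_real_, ok = FALSE))
      ld_site <- sum(log1p(ev))
    } else {
      Ssym <- Ip + U %*% W %*% t(U)
      chS <- tryCatch(chol(Ssym), error = function(e) NULL)
      if (is.null(chS)) return(list(value = NA_real_, ok = FALSE))
      ld_site <- 2 * sum(log(diag(chS)))
    }
    corr <- as.numeric(t(u) %*% W %*% solve(Ip + M %*% W, u))
    total <- total + ld + ld_site + q - corr + nobs * log(2 * pi)
  }
  list(value = total, ok = TRUE)
}

#' Full-information maximum-likelihood -2 log-likelihood
#'
#' Evaluates twice the negative Gaussian log-likelihood of the multilevel
#' variance-components mediation SEM on the observed entries only
#' (pattern-wise marginalization over missing data), summing over site
#' blocks. The shared site component is handled exactly as a rank-p update
#' of the block-diagonal family covariance. A non-positive-definite implied
#' covariance at the evaluation point yields a large penalized value with
#' the `"pd_failure"` attribute set, which keeps numerical optimizers in
#' bounds.
#'
#' @param model a [path_model()].
#' @param params list with `mu` (per-phenotype means), `paths` (named free
#'   path values), `components` (list of [variance_components()] per
#'   phenotype) and optional `contralateral` correlations (`left`, `right`,
#'   `rA`, `rC`, `rE`).
#' @param data a [fiml_data()] object.
#' @return Scalar `-2 ln L`.
#' @export
fiml_neg2ll <- function(model, params, data) {
  if (!inherits(data, "fiml_data")) stop_field("data", "must be a fiml_data")
  if (!identical(data$phenotypes, model$phenotypes))
    stop("data phenotypes do not match the model (order matters)")
  B <- build_path_matrix(paths_from_free(model, unlist(params$paths)),
                         model$phenotypes)
  G <- path_solve(B)
  ctr <- params$contralateral %||% NULL
  PA <- psi_component(params$components, "var_A", ctr)
  PC <- psi_component(params$components, "var_C", ctr)
  PE <- psi_component(params$components, "var_E", ctr)
  PS <- psi_component(params$components, "var_S", ctr)
  W <- G %*% PS %*% t(G)
  mu <- params$mu %||% rep(0, data$p)
  out <- fiml_core(data, G, PA, PC, PE, W, mu)
  if (!out$ok) {
    val <- 1e12
    attr(val, "pd_failure") <- TRUE
    return(val)
  }
  out$value
}
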