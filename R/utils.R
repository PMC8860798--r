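# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prop <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_field(field, "must be a single proportion in [0, 1]")
  x
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop_field(field, "must be a single non-negative integer")
  as.integer(x)
}

# Gauss-Hermite rule rescaled for integration against the standard normal
# density: sum(w * f(nodes)) ~ E[f(Z)], Z ~ N(0,1).
normal_quadrature <- function(n) {
  gh <- statmod::gauss.quad(n, kind = "hermite")
  list(nodes = gh$nodes * sqrt(2), weights = gh$weights / sqrt(pi))
}

logistic_2pl <- function(theta, discrimination, difficulty) {
  stats::plogis(discrimination * (theta - difficulty))
}

# scaling constant linking the logistic 2PL slope to a normal-ogive-style
# standardized loading: lambda = (a/D) / sqrt(1 + (a/D)^2)
IRT_SCALING <- 1.702

discrimination_to_loading <- function(a, D = IRT_SCALING) {
  astar <- a / D
  astar / sqrt(1 + astar^2)
}

loading_to_discrimination <- function(lambda, D = IRT_SCALING) {
  if (any(abs(lambda) >= 1)) stop("standardized loadings must lie in (-1, 1)")
  D * lambda / sqrt(1 - lambda^2)
}

symmetric_or_stop <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || max(abs(m - t(m))) > tol)
    stop("matrix must be symmetric")
  (m + t(m)) / 2
}
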