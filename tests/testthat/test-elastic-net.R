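test_that("the objective reduces to RSS limits and a hand-computed value", {
  X <- matrix(c(1, 2, 3), ncol = 1)
  y <- c(1, 2, 2)
  beta <- 0.4; b0 <- 0.5
  r <- y - b0 - X * 0.4
  expect_equal(en_objective(beta, b0, X, y, lambda = 0, alpha = 0.5),
               sum(r^2))
  expect_equal(en_objective(0, mean(y), X, y, lambda = 3, alpha = 1),
               sum((y - mean(y))^2))
  # hand arithmetic: RSS + lambda * |beta| at alpha = 1
  expect_equal(en_objective(beta, b0, X, y, lambda = 2, alpha = 1),
               sum(r^2) + 2 * 0.4)
  expect_error(en_objective(beta, b0, X, y, lambda = -1, alpha = 1), "lambda")
})

test_that("the path hits the full-shrinkage and unpenalized limits", {
  set.seed(301)
  n <- 120; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% c(1, -0.5, rep(0, p - 2)) + rnorm(n)
  fit <- fit_en_path(X, y, alpha = 0.7)
  expect_true(all(fit$beta[, 1] == 0))               # lambda_max zeroes all
  fit0 <- fit_en_path(X, y, alpha = 0.7, lambda = c(1e-4, 0), tol = 1e-12)
  ols <- unname(coef(lm(y ~ X)))
  expect_equal(unname(fit0$beta[, 2]), ols[-1], tolerance = 1e-8)
  expect_equal(unname(fit0$intercept[2]), ols[1], tolerance = 1e-8)
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  set.seed(303)
  n <- 64; p <- 8
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))   # orthonormal, X'X = I
  Q <- sweep(Q, 2, colMeans(Q))               # centered; columns stay near-orthonormal
  Q <- qr.Q(qr(Q))
  y <- rnorm(n)
  y <- y - mean(y)
  b_ols <- as.numeric(crossprod(Q, y))
  for (alpha in c(1, 0.5)) {
    for (lam in c(0.05, 0.2)) {
      fit <- fit_en_path(Q, y, alpha = alpha, lambda = lam,
                         standardize = FALSE, tol = 1e-13)
      # minimizer of sum((y - Q b)^2) + lam ((1-a)/2 b^2 + a |b|) with Q'Q = I
      expected <- sign(b_ols) * pmax(abs(b_ols) - lam * alpha / 2, 0) /
        (1 + lam * (1 - alpha) / 2)
      expect_equal(unname(fit$beta[, 1]), expected, tolerance = 1e-8)
    }
  }
})

test_that("the ridge limit matches the closed-form ridge solution", {
  set.seed(305)
  n <- 80; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  y <- as.numeric(X %*% rnorm(p) + rnorm(n)); y <- y - mean(y)
  lam <- 3.7
  fit <- fit_en_path(X, y, alpha = 0, lambda = lam, standardize = FALSE,
                     tol = 1e-13)
  closed <- solve(crossprod(X) + lam / 2 * diag(p), crossprod(X, y))
  expect_equal(unname(fit$beta[, 1]), as.numeric(closed), tolerance = 1e-8)
})

test_that("KKT conditions hold along the path for mixed penalties", {
  set.seed(307)
  n <- 150; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% c(2, -1, rep(0, p - 2)) + rnorm(n))
  for (alpha in c(0.2, 0.6, 1)) {
    fit <- fit_en_path(X, y, alpha = alpha, nlambda = 30, tol = 1e-12)
    viol <- vapply(seq_along(fit$lambda), function(l)
      twinmed:::en_kkt_violation(X, y, fit, l), numeric(1))
    expect_lt(max(viol), 1e-6)
  }
})

test_that("nonzero-coefficient counts shrink as lambda grows", {
  set.seed(309)
  X <- matrix(rnorm(200 * 10), 200, 10)
  y <- as.numeric(X %*% c(1.5, 1, 0.5, rep(0, 7)) + rnorm(200))
  fit <- fit_en_path(X, y, alpha = 0.9, nlambda = 50)
  expect_false(is.unsorted(fit$df))     # lambda decreases along the path
})

test_that("identical predictors receive equal coefficients under ridge mixing", {
  set.seed(311)
  n <- 100
  x <- rnorm(n)
  X <- cbind(x, x, rnorm(n))
  y <- as.numeric(2 * x + rnorm(n))
  fit <- fit_en_path(X, y, alpha = 0.5, lambda = 5, tol = 1e-13)
  expect_lt(abs(fit$beta[1, 1] - fit$beta[2, 1]), 1e-6)
})

test_that("coordinate descent agrees with glmnet under the lambda conversion", {
  skip_if_not_installed("glmnet")
  set.seed(313)
  n <- 200; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% c(1, -0.7, 0.4, rep(0, p - 3)) + rnorm(n))
  # glmnet standardizes the response internally (population sd), which
  # rescales its ridge penalty; with unit-variance y both objectives agree
  # under lambda_here = 2 n lambda_glmnet
  y <- y / sqrt(mean((y - mean(y))^2))
  lam_g <- c(0.4, 0.1, 0.02)
  for (alpha in c(0.3, 1)) {
    gn <- glmnet::glmnet(X, y, alpha = alpha, lambda = lam_g,
                         thresh = 1e-14, standardize = TRUE)
    fit <- fit_en_path(X, y, alpha = alpha, lambda = lam_g * 2 * n,
                       tol = 1e-13)
    expect_equal(unname(fit$beta), unname(as.matrix(gn$beta)),
                 tolerance = 1e-6)
  }
})

test_that("cross-validation under pure noise selects the empty model at lambda_1se", {
  set.seed(315)
  n <- 150; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  cv <- cross_validate(X, y, en_config(alpha_grid = c(0.8, 1), k_folds = 5,
                                       nlambda = 40, seed = 9))
  b <- cv$best
  n_at_1se <- sum(b$path$beta[, which(b$lambda == b$lambda_1se)[1]] != 0)
  expect_lte(n_at_1se, 1)
  # intercept-only limit: CV error at the largest lambda is about var(y)
  expect_lt(abs(b$cv_mse[1] - var(y)) / var(y), 0.15)
})

test_that("a perfect noiseless signal is always selected at lambda_min", {
  set.seed(317)
  n <- 100; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(2 * X[, 1])
  for (alpha in c(0.25, 0.75, 1)) {
    cv <- cross_validate(X, y, en_config(alpha_grid = alpha, k_folds = 5,
                                         nlambda = 30, seed = 11))
    sel <- select_mediators(cv, max_mse_increase = 0)
    expect_true("x1" %in% sel)
    expect_equal(sel[1], "x1")
  }
})

test_that("mediator selection recovers a planted support", {
  set.seed(319)
  n <- 1500; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  true_set <- paste0("x", 1:5)
  beta <- c(0.25, -0.2, 0.2, 0.15, -0.15, rep(0, p - 5))
  y <- as.numeric(X %*% beta + rnorm(n))
  cv <- cross_validate(X, y, en_config(alpha_grid = c(0.8, 1), k_folds = 5,
                                       nlambda = 40, seed = 13))
  sel <- select_mediators(cv)
  sensitivity <- mean(true_set %in% sel)
  expect_gte(sensitivity, 0.8)
  # the strongest true predictors outrank the noise in the importance order
  expect_true(all(sel[1:3] %in% true_set))
})

test_that("family-stratified folds never split relatives", {
  set.seed(321)
  n <- 120
  fam <- rep(1:60, each = 2)
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rnorm(n)
  cv <- cross_validate(X, y, en_config(alpha_grid = 1, k_folds = 4,
                                       nlambda = 10, seed = 15),
                       family_id = fam)
  expect_true(all(tapply(cv$fold, fam, function(z) length(unique(z))) == 1))
})

test_that("configuration invariants are enforced", {
  expect_error(en_config(alpha_grid = c(-0.1, 0.5)), "alpha")
  expect_error(en_config(k_folds = 1), "k_folds")
  expect_error(fit_en_path(matrix(1:4, 2), 1:2, alpha = 0.5,
                           lambda = c(1, 2)), "decreasing")
})
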