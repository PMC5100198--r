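test_that("design bookkeeping: column order, degenerate M = 1, dimensions", {
  set.seed(2)
  Y <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("P1", "P2", "P3")))
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("S1", "S2")))
  d <- build_design(Y, X, i = 2)
  expect_identical(colnames(d$W), c("P1", "P3", "S1", "S2"))
  expect_identical(d$W[, "P1"], Y[, 1])
  expect_identical(d$W[, "P3"], Y[, 3])
  d1 <- build_design(Y[, 1, drop = FALSE], X, i = 1)
  expect_identical(colnames(d1$W), c("S1", "S2"))
  for (case in list(c(4, 3), c(2, 5))) {
    Yr <- matrix(rnorm(20 * case[1]), 20, case[1])
    Xr <- matrix(rnorm(20 * case[2]), 20, case[2])
    expect_equal(ncol(build_design(Yr, Xr, 1)$W), case[1] - 1 + case[2])
  }
})

test_that("GLS estimate equals the explicit two-stage procedure", {
  # The full design [Y_{-i} X] projected on the instrument span is always
  # rank deficient (rank K < M - 1 + K), so the identity is checked on
  # well-posed restricted designs: endogenous columns plus a subset of the
  # exogenous ones, as used by the post-selection refits.
  set.seed(3)
  for (rep in 1:5) {
    n <- 60
    Y <- matrix(rnorm(n * 3), n, 3)
    X <- matrix(rnorm(n * 6), n, 6)
    i <- sample(3, 1)
    W_S <- cbind(Y[, -i, drop = FALSE], X[, 1:3])
    M_inst <- solve(crossprod(X))
    A <- crossprod(X, W_S)
    eq5 <- solve(t(A) %*% M_inst %*% A,
                 t(A) %*% M_inst %*% crossprod(X, Y[, i]))
    # stage 1: regress the endogenous columns on X; stage 2: regress y_i on
    # the fitted values and the included exogenous columns
    Pi_hat <- solve(crossprod(X), crossprod(X, Y[, -i, drop = FALSE]))
    What <- cbind(X %*% Pi_hat, X[, 1:3])
    eq6 <- solve(crossprod(What), crossprod(What, Y[, i]))
    expect_equal(drop(eq5), drop(eq6), tolerance = 1e-8)
  }
})

test_that("GLS degenerate cases: OLS reduction, zero response, singularity", {
  set.seed(4)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rnorm(n)
  d <- build_design(matrix(y, ncol = 1), X, 1)  # M = 1: W = X
  expect_equal(unname(gls_estimate(d)),
               drop(solve(crossprod(X), crossprod(X, y))), tolerance = 1e-8)
  d0 <- build_design(matrix(0, n, 1), X, 1)
  expect_equal(unname(gls_estimate(d0)), rep(0, 3))
  # M > 1 makes W'X(X'X)^-1 X'W rank deficient: must advise a way out
  Y2 <- matrix(rnorm(n * 2), n, 2)
  expect_error(gls_estimate(build_design(Y2, X, 1)), "ridge|FPC")
})

test_that("ADMM at lambda 0 matches GLS; full shrinkage at lambda_max", {
  set.seed(5)
  n <- 50
  Y <- matrix(rnorm(n), n, 1)
  X <- matrix(rnorm(n * 4), n, 4)
  d <- build_design(Y, X, 1)
  sol0 <- admm_lasso(d, lambda = 0)
  expect_equal(unname(sol0$coef), unname(gls_estimate(d)),
               tolerance = 1e-6)
  quad <- pleiosem:::design_quadratic(d)
  lmax <- pleiosem:::lambda_zero_threshold(quad)
  solmax <- admm_lasso(d, lambda = lmax * 1.0001)
  expect_identical(unname(solmax$coef), rep(0, 4))
  solbig <- admm_lasso(d, lambda = lmax * 0.9)
  expect_gt(sum(solbig$coef != 0), 0)
})

test_that("ADMM objective matches a coordinate-descent lasso oracle", {
  skip_if_not_installed("glmnet")
  set.seed(6)
  for (rep in 1:20) {
    n <- 50
    Y <- matrix(rnorm(n * 3), n, 3)
    X <- matrix(rnorm(n * 6), n, 6)
    d <- build_design(scale(Y, scale = FALSE), scale(X, scale = FALSE), 1)
    quad <- pleiosem:::design_quadratic(d)
    lambda <- pleiosem:::lambda_zero_threshold(quad) *
      stats::runif(1, 0.02, 0.5)
    sol <- admm_lasso(d, lambda)
    # reformulate: (X'X)^-1 = L L' gives f = ||L'b - L'A delta||^2
    LA <- crossprod(d$instrument$L, d$A)
    Lb <- drop(crossprod(d$instrument$L, d$b))
    K <- nrow(LA)
    cd <- as.numeric(stats::coef(glmnet::glmnet(
      LA, Lb, lambda = lambda / (2 * K), standardize = FALSE,
      intercept = FALSE, thresh = 1e-14)))[-1]
    obj <- function(delta) {
      pleiosem:::gls_objective(quad, delta) + lambda * sum(abs(delta))
    }
    expect_equal(sol$objective, obj(cd), tolerance = 1e-6)
  }
})

test_that("soft-threshold zeros are exact and L1 norm shrinks with lambda", {
  set.seed(7)
  n <- 80
  Y <- matrix(rnorm(n * 2), n, 2)
  X <- matrix(rnorm(n * 5), n, 5)
  d <- build_design(Y, X, 1)
  quad <- pleiosem:::design_quadratic(d)
  lmax <- pleiosem:::lambda_zero_threshold(quad)
  l1 <- c()
  for (fr in c(0.5, 0.2, 0.1, 0.05, 0.01)) {
    sol <- admm_lasso(d, lmax * fr)
    zeros <- sol$coef[sol$coef == 0]
    expect_true(all(identical(unique(unname(zeros)), 0) ||
                      length(zeros) == 0))
    l1 <- c(l1, sum(abs(sol$coef)))
  }
  expect_true(all(diff(l1) >= -1e-8))  # non-increasing in lambda
})

test_that("unpenalized refit on the true support recovers generating
           coefficients", {
  set.seed(8)
  sys <- toy_system(n = 2000, M = 3, K = 3)
  fit <- fit_s2sem(sys$Y, sys$X, lambda = 0.05 * nrow(sys$Y))
  for (i in 1:3) {
    truth <- c(sys$Gamma[-i, i], sys$B[, i])
    cols <- which(truth != 0)
    ref <- pleiosem:::refit_equation(fit, i, cols)
    expect_equal(unname(ref$delta), unname(truth[cols]), tolerance = 0.05)
  }
})

test_that("full fit: no-signal shrinkage, equivariance under phenotype
           permutation", {
  set.seed(9)
  n <- 200
  Y <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("A", "B", "C")))
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("s", 1:4)))
  fit <- fit_s2sem(Y, X, lambda = 1e6)
  expect_equal(sum(fit$support_Gamma), 0L)
  expect_equal(sum(fit$support_B), 0L)
  expect_true(all(diag(fit$Gamma) == -1))

  sys <- toy_system(n = 400, M = 3, K = 3)
  lam <- 0.02 * nrow(sys$Y)
  f1 <- fit_s2sem(sys$Y, sys$X, lambda = lam)
  perm <- c(2, 3, 1)
  f2 <- fit_s2sem(sys$Y[, perm], sys$X, lambda = lam)
  expect_equal(f2$Gamma[fit_labels <- colnames(sys$Y)[perm],
                        fit_labels],
               f1$Gamma[fit_labels, fit_labels], tolerance = 1e-6)
  expect_equal(f2$B[, fit_labels], f1$B[, fit_labels], tolerance = 1e-6)
})

test_that("cross-validation: argmin property, singleton grid, noise selects
           the largest penalty, fold-count guard", {
  set.seed(10)
  sys <- toy_system(n = 150, M = 2, K = 3)
  cv <- cross_validate_lambda(sys$Y, sys$X, seed = 1)
  by_eq <- split(cv$cv, cv$cv$phenotype)
  for (tab in by_eq) {
    expect_equal(tab$cv_score[tab$selected], min(tab$cv_score))
    expect_equal(cv$lambda[[unique(tab$phenotype)]],
                 tab$lambda[tab$selected])
  }
  cv1 <- cross_validate_lambda(sys$Y, sys$X, grid = 3.3, seed = 1)
  expect_true(all(cv1$lambda == 3.3))

  # pure-noise response: the all-zero model is competitive, so the largest
  # grid value should win for most seeds
  wins <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    Yn <- matrix(rnorm(120), 120, 1)
    Xn <- matrix(rnorm(120 * 3), 120, 3)
    cvn <- cross_validate_lambda(Yn, Xn, seed = s)
    tab <- cvn$cv
    if (match(tab$lambda[tab$selected], tab$lambda) <= 2) wins <- wins + 1
  }
  expect_gte(wins, 3)

  expect_error(cross_validate_lambda(sys$Y[1:3, ], sys$X[1:3, ], folds = 5),
               "folds")
})

test_that("CV fold assignment is deterministic given the seed", {
  set.seed(11)
  sys <- toy_system(n = 120, M = 2, K = 3)
  cv_a <- cross_validate_lambda(sys$Y, sys$X, seed = 42)
  cv_b <- cross_validate_lambda(sys$Y, sys$X, seed = 42)
  expect_identical(cv_a$cv, cv_b$cv)
})
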