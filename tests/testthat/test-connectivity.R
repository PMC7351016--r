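test_that("pearson connectivity matches direct product-moment evaluation", {
  # affine dependence
  V <- cbind(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10), c(5, 4, 3, 2, 1))
  W <- pearson_connectivity(V)$weights
  expect_equal(W[1, 2], 1)
  expect_equal(W[1, 3], -1)
  expect_equal(diag(W), rep(0, 3))

  # quadrature pair over a full period is near-orthogonal
  tt <- seq_len(100)
  V2 <- cbind(sin(2 * pi * tt / 100), cos(2 * pi * tt / 100))
  expect_lt(abs(pearson_connectivity(V2)$weights[1, 2]), 0.05)

  # entrywise agreement with the explicit summation oracle
  set.seed(10)
  V3 <- matrix(rnorm(60 * 6), 60, 6)
  W3 <- pearson_connectivity(V3)$weights
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(W3[i, j], oracle_pearson(V3[, i], V3[, j]),
                 tolerance = 1e-10)
  expect_equal(W3, t(W3))
})

test_that("zero-variance regions get zero rows with a warning, not an error", {
  set.seed(11)
  V <- cbind(rnorm(30), rep(2, 30), rnorm(30))
  expect_warning(W <- pearson_connectivity(V)$weights, "zero variance")
  expect_equal(W[2, ], rep(0, 3))
  expect_equal(W[, 2], rep(0, 3))
  expect_false(W[1, 3] == 0)
})

test_that("lasso solves the one-predictor problem in closed form", {
  set.seed(12)
  a <- rnorm(40)
  y <- 2 * a + rnorm(40)
  ac <- a - mean(a)
  yc <- y - mean(y)
  for (lam in c(0, 0.5, 5, 50)) {
    got <- as.numeric(lasso_regress(y, matrix(a), lam))
    z <- sum(ac * yc)
    want <- sign(z) * max(abs(z) - lam, 0) / sum(ac^2)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("lambda at or above the shrink threshold gives the exact zero vector", {
  set.seed(13)
  A <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  lmax <- lasso_lambda_max(y, A)
  expect_identical(as.numeric(lasso_regress(y, A, lmax)), rep(0, 5))
  expect_identical(as.numeric(lasso_regress(y, A, lmax * 2)), rep(0, 5))
  # just below the threshold something activates
  expect_gt(sum(as.numeric(lasso_regress(y, A, lmax * 0.99)) != 0), 0)
})

test_that("lasso satisfies stationarity and matches the convex oracle", {
  skip_if_not_installed("glmnet")
  set.seed(14)
  for (rep in 1:10) {
    t_len <- sample(10:30, 1)
    p <- sample(2:6, 1)
    A <- scale(matrix(rnorm(t_len * p), t_len, p), scale = FALSE)
    y <- as.numeric(scale(rnorm(t_len), scale = FALSE))
    lam <- runif(1, 0.1, 2)
    alpha <- as.numeric(lasso_regress(y, A, lam, center = FALSE))
    grad <- as.numeric(crossprod(A, y - A %*% alpha))
    expect_lt(max(abs(grad)) - lam, 1e-6)
    active <- alpha != 0
    if (any(active)) {
      expect_lt(max(abs(grad[active] - lam * sign(alpha[active]))), 1e-6)
    }
    ob <- lasso_objective(y, A, oracle_lasso_coefs(y, A, lam), lam)
    expect_equal(lasso_objective(y, A, alpha, lam), ob,
                 tolerance = 1e-6)
  }
})

test_that("lasso sparsity is monotone in lambda and reaches OLS as lambda -> 0", {
  set.seed(15)
  A <- matrix(rnorm(50 * 6), 50, 6)
  y <- A %*% c(1, -1, 0.5, 0, 0, 0) + rnorm(50)
  lams <- c(0.5, 2, 8, 32)
  nnz <- vapply(lams, function(l)
    sum(as.numeric(lasso_regress(y, A, l)) != 0), numeric(1))
  expect_true(all(diff(nnz) <= 0))

  # lambda -> 0 limit: objective gap to least squares < 1e-6
  Ac <- scale(A, scale = FALSE)
  yc <- as.numeric(scale(y, scale = FALSE))
  ols <- as.numeric(solve(crossprod(Ac), crossprod(Ac, yc)))
  al <- as.numeric(lasso_regress(y, A, 1e-8))
  expect_lt(lasso_objective(yc, Ac, al, 1e-8) -
              lasso_objective(yc, Ac, ols, 1e-8), 1e-6)
})

test_that("symmetrization rules behave as defined", {
  B <- matrix(0, 3, 3)
  B[1, 2] <- 0.5; B[2, 1] <- -0.2
  Wmax <- symmetrize(B, "max_abs")
  expect_equal(Wmax[1, 2], 0.5)
  expect_equal(Wmax[2, 1], 0.5)
  Wmean <- symmetrize(B, "mean")
  expect_equal(Wmean[1, 2], 0.15)
  expect_equal(Wmean[2, 1], 0.15)

  # ties keep the upper-triangle entry
  B2 <- matrix(0, 2, 2); B2[1, 2] <- 0.3; B2[2, 1] <- -0.3
  expect_equal(symmetrize(B2, "max_abs")[1, 2], 0.3)

  # already-symmetric input is a fixed point of both rules
  S <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  expect_equal(symmetrize(S, "max_abs"), S)
  expect_equal(symmetrize(S, "mean"), S)
  expect_error(symmetrize(B, "median"), "arg")
})

test_that("l1 connectivity finds the planted dependence and is symmetric", {
  set.seed(16)
  x2 <- rnorm(100)
  V <- cbind(x2 + 0.05 * rnorm(100), x2, rnorm(100))
  cm <- l1_connectivity(V, lasso_config(lam_fraction = 0.05))
  W <- cm$weights
  expect_gt(abs(W[1, 2]), 10 * abs(W[1, 3]))
  expect_equal(W, t(W))
  expect_equal(unname(diag(W)), rep(0, 3))
  expect_equal(cm$method, "l1")
  expect_true(is.numeric(cm$lambda_used))
})

test_that("a fixed lambda above every region's threshold zeroes the matrix", {
  set.seed(17)
  V <- matrix(rnorm(60 * 5), 60, 5)
  Vc <- sweep(V, 2, colMeans(V))
  biggest <- max(abs(crossprod(Vc) - diag(diag(crossprod(Vc)))))
  cm <- l1_connectivity(V, lasso_config(lam = biggest * 1.01,
                                        lam_policy = "fixed"))
  expect_equal(cm$weights, matrix(0, 5, 5), ignore_attr = TRUE)
})

test_that("select_lambda obeys its policy and drives sparsity monotonically", {
  set.seed(18)
  spec <- cohort_spec(n_per_group = c(g = 1), n_regions = 20,
                      n_timepoints = 155,
                      module_partition = rep(1:4, each = 5),
                      group_deltas = c(g = 0), seed = 7)
  ts <- generate_cohort(spec)$subjects[[1]]

  expect_equal(select_lambda(ts, lasso_config(lam = 0.7, lam_policy = "fixed")),
               0.7)
  expect_error(lasso_config(lam_fraction = 1.5), "lam_fraction")

  # fraction 1 -> everything shrinks to zero
  cm1 <- l1_connectivity(ts, lasso_config(lam_fraction = 1))
  expect_true(all(cm1$weights == 0))

  # nonzero fraction decreases as the penalty fraction rises
  frac_nonzero <- vapply(c(0.1, 0.3, 0.5), function(f) {
    W <- l1_connectivity(ts, lasso_config(lam_fraction = f))$weights
    mean(W[upper.tri(W)] != 0)
  }, numeric(1))
  expect_true(all(diff(frac_nonzero) <= 0))
  expect_gt(frac_nonzero[1], 0)
  expect_lt(frac_nonzero[1], 1)
})
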