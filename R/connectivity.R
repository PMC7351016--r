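# Weighted connectivity matrices from one subject's regional time series:
# full Pearson correlation, or per-region L1-regularized (lasso)
# regression in which each region's series is modeled as a sparse linear
# combination of all other regions' series.

#' Weighted connectivity matrix
#'
#' @param weights M x M numeric matrix with zero diagonal.
#' @param method `"pearson"` or `"l1"`.
#' @param lambda_used Regularization value actually applied (`l1` only).
#' @param symmetrization Rule used to symmetrize (`l1` only).
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights, method = c("pearson", "l1"),
                                lambda_used = NULL, symmetrization = NULL) {
  method <- match.arg(method)
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stopf("weights must be a square matrix")
  if (any(diag(weights) != 0)) stopf("diagonal must be exactly 0")
  structure(list(weights = weights, method = method,
                 lambda_used = lambda_used, symmetrization = symmetrization),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  m <- ncol(x$weights)
  off <- x$weights[upper.tri(x$weights) | lower.tri(x$weights)]
  cat(sprintf("<connectivity_matrix> method = %s, M = %d, zero off-diagonal = %.1f%%\n",
              x$method, m, 100 * mean(off == 0)))
  if (!is.null(x$lambda_used))
    cat(sprintf("  lambda = %.6g, symmetrization = %s\n",
                x$lambda_used, x$symmetrization))
  invisible(x)
}

#' Pearson correlation connectivity
#'
#' Entry (i, j) is the Pearson correlation coefficient between the i-th
#' and j-th regional series; the matrix is symmetric and the diagonal is
#' forced to zero (self-connections are excluded from the graph). A
#' region with zero temporal variance gets a zero row and column with a
#' warning rather than an error, so degenerate inputs still flow.
#'
#' @param ts A [ts_matrix()] or numeric T x M matrix.
#' @return A [connectivity_matrix()] with `method = "pearson"`.
#' @export
pearson_connectivity <- function(ts) {
  V <- ts_values(ts)
  m <- ncol(V)
  v <- apply(V, 2, stats::var)
  bad <- which(v == 0 | !is.finite(v))
  W <- matrix(0, m, m)
  good <- setdiff(seq_len(m), bad)
  if (length(bad))
    warnf("%d region(s) with zero variance: %s; their connections are set to 0",
          length(bad), paste(bad, collapse = ", "))
  if (length(good) >= 2)
    W[good, good] <- stats::cor(V[, good, drop = FALSE])
  diag(W) <- 0
  dimnames(W) <- list(colnames(V), colnames(V))
  connectivity_matrix(W, method = "pearson")
}

#' Lasso configuration for L1 connectivity
#'
#' @param lam Fixed regularization weight (used when
#'   `lam_policy = "fixed"`); must be `>= 0`.
#' @param lam_policy `"fraction_of_max"` scales the penalty to the data:
#'   lambda = `lam_fraction` times the largest per-region shrink-to-zero
#'   threshold `max_j |a_j' y_p|`, giving a subject-comparable sparsity
#'   level. `"fixed"` uses `lam` as given.
#' @param lam_fraction Fraction in `(0, 1]` for the `fraction_of_max`
#'   policy; at 1 every region's solution is exactly zero.
#' @param tol Convergence tolerance on the stationarity (subgradient)
#'   conditions, relative to the data scale.
#' @param max_iter Maximum coordinate-descent sweeps per region.
#' @param symmetrization `"max_abs"` keeps, for each pair, whichever of
#'   the two directed coefficients has larger magnitude; `"mean"`
#'   averages them.
#' @return Object of class `lasso_config`.
#' @export
lasso_config <- function(lam = NULL,
                         lam_policy = c("fraction_of_max", "fixed"),
                         lam_fraction = 0.1,
                         tol = 1e-8, max_iter = 10000L,
                         symmetrization = c("max_abs", "mean")) {
  lam_policy <- match.arg(lam_policy)
  symmetrization <- match.arg(symmetrization)
  if (lam_policy == "fixed") {
    if (!is_number(lam) || lam < 0)
      stopf("lam_policy = 'fixed' requires a single lam >= 0")
  }
  if (!is_number(lam_fraction) || lam_fraction <= 0 || lam_fraction > 1)
    stopf("lam_fraction must lie in (0, 1], got %s", format(lam_fraction))
  if (!is_number(tol) || tol <= 0) stopf("tol must be > 0")
  if (!is_count(max_iter)) stopf("max_iter must be >= 1")
  structure(list(lam = lam, lam_policy = lam_policy,
                 lam_fraction = lam_fraction, tol = tol,
                 max_iter = as.integer(max_iter),
                 symmetrization = symmetrization),
            class = "lasso_config")
}

# Core cyclic coordinate descent on the Gram formulation of
#   f(alpha) = 1/2 ||y - A alpha||^2 + lam ||alpha||_1 ,
# where G = A'A and c0 = A'y. Returns the coefficient vector with the
# number of sweeps and the final stationarity violation as attributes.
lasso_cd <- function(G, c0, lam, tol = 1e-8, max_iter = 10000L) {
  p <- length(c0)
  alpha <- numeric(p)
  gjj <- diag(G)
  scale <- max(1, max(abs(c0)))
  grad <- c0                       # c0 - G alpha, maintained incrementally
  kkt_violation <- function() {
    v_zero <- pmax(abs(grad) - lam, 0)
    v_act <- abs(grad - lam * sign(alpha))
    max(ifelse(alpha == 0, v_zero, v_act))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    delta_max <- 0
    for (j in seq_len(p)) {
      if (gjj[j] <= 0) next       # zero-variance predictor stays at 0
      z <- grad[j] + gjj[j] * alpha[j]
      aj_new <- sign(z) * max(abs(z) - lam, 0) / gjj[j]
      d <- aj_new - alpha[j]
      if (d != 0) {
        grad <- grad - G[, j] * d
        alpha[j] <- aj_new
        delta_max <- max(delta_max, abs(d))
      }
    }
    kkt <- kkt_violation()
    if (kkt <= tol * scale) break
    if (it >= max_iter)
      stopf("lasso did not converge in %d sweeps (stationarity violation %.3g, tolerance %.3g)",
            max_iter, kkt, tol * scale)
  }
  structure(alpha, iterations = it, kkt = kkt)
}

#' Lasso regression of one series on a predictor matrix
#'
#' Solves `min_alpha 1/2 ||y - A alpha||^2 + lam ||alpha||_1` by cyclic
#' coordinate descent with soft thresholding. Columns of `predictors`
#' and the response are mean-centered before the fit (removing the
#' intercept the model omits); coefficients refer to the centered
#' predictors. The returned solution satisfies the subgradient
#' optimality conditions of the objective to within `tol` (relative to
#' the data scale): `|a_j'(y - A alpha)| <= lam` for every j, with
#' equality and sign agreement wherever `alpha_j != 0`.
#'
#' @param response Numeric vector of length T.
#' @param predictors T x p numeric matrix.
#' @param lam Regularization weight `>= 0`.
#' @param tol,max_iter Convergence control, see [lasso_config()].
#' @param center Mean-center response and predictor columns first
#'   (default `TRUE`).
#' @return Numeric coefficient vector of length p, with attributes
#'   `iterations` and `kkt` (final stationarity violation).
#' @export
lasso_regress <- function(response, predictors, lam,
                          tol = 1e-8, max_iter = 10000L, center = TRUE) {
  y <- as.numeric(response)
  A <- as.matrix(predictors)
  if (nrow(A) != length(y))
    stopf("predictors have %d rows but the response has length %d",
          nrow(A), length(y))
  if (length(y) < 2) stopf("need T >= 2 time points")
  if (!is_number(lam) || lam < 0) stopf("lam must be >= 0")
  if (center) {
    y <- y - mean(y)
    A <- sweep(A, 2, colMeans(A))
  }
  lasso_cd(crossprod(A), crossprod(A, y), lam,
           tol = tol, max_iter = max_iter)
}

#' Shrink-to-zero penalty threshold
#'
#' The smallest lambda at which the lasso solution for this region is
#' exactly zero: `max_j |a_j' y|` on the mean-centered data.
#'
#' @inheritParams lasso_regress
#' @return A single non-negative number.
#' @export
lasso_lambda_max <- function(response, predictors, center = TRUE) {
  y <- as.numeric(response)
  A <- as.matrix(predictors)
  if (center) {
    y <- y - mean(y)
    A <- sweep(A, 2, colMeans(A))
  }
  max(abs(crossprod(A, y)))
}

#' Choose the regularization weight for a subject
#'
#' `fixed` policy returns `cfg$lam`. `fraction_of_max` returns
#' `cfg$lam_fraction` times the largest shrink-to-zero threshold over all
#' regions, so the same fraction gives comparable sparsity across
#' subjects with different signal scales.
#'
#' @param ts A [ts_matrix()] or numeric T x M matrix.
#' @param cfg A [lasso_config()].
#' @return The lambda value to use for every per-region fit.
#' @export
select_lambda <- function(ts, cfg = lasso_config()) {
  if (!inherits(cfg, "lasso_config")) stopf("cfg must be a lasso_config")
  if (cfg$lam_policy == "fixed") return(cfg$lam)
  V <- ts_values(ts)
  Vc <- sweep(V, 2, colMeans(V))
  C <- crossprod(Vc)
  diag(C) <- 0
  # max over regions p of max_{j != p} |a_j' y_p| is the largest
  # off-diagonal entry of the centered Gram matrix
  cfg$lam_fraction * max(abs(C))
}

#' Symmetrize an asymmetric coefficient matrix
#'
#' The per-region regressions give a directed coefficient matrix; the
#' undirected graph analysis needs a symmetric one. `max_abs` keeps, for
#' each unordered pair, whichever directed coefficient has the larger
#' magnitude (ties keep the upper-triangle entry, i < j); `mean` takes
#' the arithmetic mean of the two.
#'
#' @param asym Square numeric matrix with zero diagonal.
#' @param rule `"max_abs"` or `"mean"`.
#' @return Symmetric matrix of the same dimension.
#' @export
symmetrize <- function(asym, rule = c("max_abs", "mean")) {
  rule <- match.arg(rule)
  if (!is.matrix(asym) || nrow(asym) != ncol(asym))
    stopf("asym must be a square matrix")
  if (any(diag(asym) != 0)) stopf("diagonal must be 0 before symmetrization")
  if (rule == "mean") return((asym + t(asym)) / 2)
  up <- upper.tri(asym)
  a <- asym[up]             # entries (i, j), i < j
  b <- t(asym)[up]          # entries (j, i)
  v <- ifelse(abs(b) > abs(a), b, a)
  W <- matrix(0, nrow(asym), ncol(asym), dimnames = dimnames(asym))
  W[up] <- v
  W <- W + t(W)
  W
}

#' L1-regularized regression connectivity
#'
#' For each region p, regresses its series on the remaining M - 1 series
#' with the lasso penalty chosen by [select_lambda()]; coefficient
#' `alpha_{p <- j}` fills entry (p, j) of a directed matrix, which is then
#' symmetrized per `cfg$symmetrization`. Exact zeros in the coefficients
#' make this matrix sparse, unlike the dense correlation matrix.
#'
#' @param ts A [ts_matrix()] or numeric T x M matrix.
#' @param cfg A [lasso_config()].
#' @return A [connectivity_matrix()] with `method = "l1"` and
#'   `lambda_used` recorded.
#' @export
l1_connectivity <- function(ts, cfg = lasso_config()) {
  if (!inherits(cfg, "lasso_config")) stopf("cfg must be a lasso_config")
  V <- ts_values(ts)
  m <- ncol(V)
  if (m < 2) stopf("need at least 2 regions")
  lam <- select_lambda(ts, cfg)
  Vc <- sweep(V, 2, colMeans(V))
  G <- crossprod(Vc)
  B <- matrix(0, m, m)
  for (p in seq_len(m)) {
    fit <- tryCatch(
      lasso_cd(G[-p, -p, drop = FALSE], G[-p, p], lam,
               tol = cfg$tol, max_iter = cfg$max_iter),
      error = function(e) stopf("region %d: %s", p, conditionMessage(e)))
    B[p, -p] <- as.numeric(fit)
  }
  W <- symmetrize(B, cfg$symmetrization)
  dimnames(W) <- list(colnames(V), colnames(V))
  connectivity_matrix(W, method = "l1", lambda_used = lam,
                      symmetrization = cfg$symmetrization)
}
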