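# Independent brute-force oracles used to validate the fast
# implementations. Deliberately naive: triple loops, Floyd-Warshall,
# explicit summation.

# Clustering coefficient by exhaustive triangle-triple enumeration.
oracle_cp <- function(A) {
  m <- nrow(A)
  vals <- numeric(m)
  for (i in seq_len(m)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] == 1) tri <- tri + 1
    vals[i] <- 2 * tri / (k * (k - 1))
  }
  mean(vals)
}

# All-pairs shortest paths by Floyd-Warshall.
oracle_distances <- function(A) {
  m <- nrow(A)
  d <- matrix(Inf, m, m)
  d[A == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(m)) for (i in seq_len(m)) for (j in seq_len(m))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_lp <- function(A) {
  d <- oracle_distances(A)
  du <- d[upper.tri(d)]
  mean(du[is.finite(du)])
}

oracle_eg <- function(A) {
  if (nrow(A) < 2) return(0)
  d <- oracle_distances(A)
  du <- d[upper.tri(d)]
  mean(ifelse(is.finite(du), 1 / du, 0))
}

# Local efficiency by materializing every neighbor-induced subgraph.
oracle_eloc <- function(A) {
  m <- nrow(A)
  vals <- numeric(m)
  for (i in seq_len(m)) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    vals[i] <- oracle_eg(A[nb, nb, drop = FALSE])
  }
  mean(vals)
}

# Random symmetric 0/1 adjacency with zero diagonal.
random_adjacency <- function(m, p = 0.4) {
  A <- matrix(0L, m, m)
  A[upper.tri(A)] <- rbinom(m * (m - 1) / 2, 1, p)
  A + t(A)
}

# Pearson correlation by explicit summation of the product-moment
# formula.
oracle_pearson <- function(x, y) {
  t_len <- length(x)
  mx <- sum(x) / t_len
  my <- sum(y) / t_len
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Lasso objective value.
lasso_objective <- function(y, A, alpha, lam) {
  0.5 * sum((y - A %*% alpha)^2) + lam * sum(abs(alpha))
}

# Convex oracle for the lasso objective via glmnet at high precision
# (objectives are scale-equivalent with lambda_glmnet = lam / n).
oracle_lasso_coefs <- function(y, A, lam) {
  fit <- glmnet::glmnet(A, y, lambda = lam / length(y),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14, maxit = 1e6)
  as.numeric(stats::coef(fit))[-1]
}
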