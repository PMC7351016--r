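path_graph3 <- function() {
  A <- matrix(0L, 3, 3)
  A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1L
  binary_network(A)
}

star_graph <- function(leaves = 3) {
  A <- matrix(0L, leaves + 1, leaves + 1)
  A[1, -1] <- A[-1, 1] <- 1L
  binary_network(A)
}

complete_graph <- function(n) binary_network(1 - diag(n))

test_that("binarization keeps exactly the strongest K edges", {
  set.seed(20)
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(0.9, -0.8, 0.1, 0.7, 0.2, 0.3)
  W <- W + t(W)
  net <- binarize_at_density(W, 0.5)
  expect_equal(net$n_edges, 3L)   # round(0.5 * 6)
  # the three largest |weights| are (1,2)=0.9, (1,3)=-0.8, (1,4)=0.7
  expect_equal(net$adjacency[1, 2], 1L)
  expect_equal(net$adjacency[1, 3], 1L)
  expect_equal(net$adjacency[1, 4], 1L)
  expect_equal(net$adjacency[2, 3], 0L)

  # density 1 on an all-nonzero matrix is the complete graph
  W2 <- matrix(runif(25), 5, 5); W2 <- W2 + t(W2); diag(W2) <- 0
  expect_equal(binarize_at_density(W2, 1)$adjacency,
               complete_graph(5)$adjacency)

  # the study-scale edge count: round(0.10 * 90*89/2) = 401 on 90 nodes
  W3 <- matrix(rnorm(90 * 90), 90, 90); W3 <- W3 + t(W3); diag(W3) <- 0
  expect_equal(binarize_at_density(W3, 0.10)$n_edges, 401L)
})

test_that("binarization of an over-sparse matrix keeps what exists and warns", {
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 1] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.4
  expect_warning(net <- binarize_at_density(W, 0.5), "nonzero")
  expect_equal(net$n_edges, 2L)
  expect_equal(attr(net, "shortfall"), 6L)   # round(0.5*15) = 8 wanted
})

test_that("binarization ties at the cutoff break deterministically", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.5
  W[1, 3] <- W[3, 1] <- 0.5
  net <- binarize_at_density(W, 2 / 6)   # keep 2 of 3 tied edges
  expect_equal(net$n_edges, 2L)
  expect_equal(net$adjacency[1, 2], 1L)  # lexicographically first
  expect_equal(net$adjacency[1, 3], 1L)
  expect_equal(net$adjacency[3, 4], 0L)
})

test_that("metrics take their textbook values on canonical graphs", {
  k4 <- complete_graph(4)
  expect_equal(clustering_coefficient(k4), 1)
  expect_equal(local_efficiency(k4), 1)
  expect_equal(as.numeric(characteristic_path_length(k4)), 1)
  expect_equal(global_efficiency(k4), 1)

  st <- star_graph(3)
  expect_equal(clustering_coefficient(st), 0)
  expect_equal(local_efficiency(st), 0)

  p3 <- path_graph3()
  expect_equal(as.numeric(characteristic_path_length(p3)), 4 / 3)
  expect_equal(global_efficiency(p3), 5 / 6)

  # disconnected pair
  iso <- binary_network(matrix(0L, 2, 2))
  expect_equal(global_efficiency(iso), 0)
  expect_error(characteristic_path_length(iso), "no reachable pairs")
  expect_equal(clustering_coefficient(iso), 0)
})

test_that("all four metrics agree with brute-force oracles on random graphs", {
  set.seed(21)
  for (i in 1:50) {
    m <- sample(4:12, 1)
    A <- random_adjacency(m, runif(1, 0.2, 0.7))
    net <- binary_network(A)
    expect_equal(clustering_coefficient(net), oracle_cp(A))
    expect_equal(global_efficiency(net), oracle_eg(A))
    expect_equal(local_efficiency(net), oracle_eloc(A))
    if (sum(A) > 0)
      expect_equal(as.numeric(characteristic_path_length(net)), oracle_lp(A))
  }
})

test_that("adding an edge never decreases Eg nor increases Lp", {
  set.seed(22)
  for (i in 1:20) {
    A <- random_adjacency(8, 0.4)
    gaps <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(gaps) == 0 || sum(A) == 0) next
    pick <- gaps[sample(nrow(gaps), 1), ]
    A2 <- A
    A2[pick[1], pick[2]] <- A2[pick[2], pick[1]] <- 1L
    expect_gte(global_efficiency(binary_network(A2)),
               global_efficiency(binary_network(A)))
    d1 <- oracle_distances(A); d2 <- oracle_distances(A2)
    # per-pair distances never grow, so any reachable-pair average built
    # on a superset of reachable pairs cannot exceed the old one
    expect_true(all(d2 <= d1))
  }
})

test_that("metric ranges are respected on random graphs", {
  set.seed(23)
  for (i in 1:20) {
    A <- random_adjacency(10, runif(1, 0.1, 0.9))
    net <- binary_network(A)
    expect_gte(clustering_coefficient(net), 0)
    expect_lte(clustering_coefficient(net), 1)
    expect_gte(global_efficiency(net), 0)
    expect_lte(global_efficiency(net), 1)
    expect_gte(local_efficiency(net), 0)
    expect_lte(local_efficiency(net), 1)
    if (sum(A) > 0)
      expect_gte(as.numeric(characteristic_path_length(net)), 1)
  }
})

test_that("rewiring preserves the degree sequence and edge count", {
  set.seed(24)
  for (i in 1:20) {
    net <- random_network(20, 0.25, seed = 100 + i)
    rw <- suppressWarnings(
      rewire_degree_preserving(net, null_config(seed = 200 + i)))
    expect_equal(colSums(rw$adjacency), colSums(net$adjacency))
    expect_equal(rw$n_edges, net$n_edges)
  }
})

test_that("a triangle cannot be rewired and is returned unchanged", {
  tri <- complete_graph(3)
  expect_warning(rw <- rewire_degree_preserving(tri, null_config(seed = 1)),
                 "unchanged")
  expect_equal(rw$adjacency, tri$adjacency)
})

test_that("small-world indices are ratios with the definitional identity", {
  net <- ring_lattice_network(40, 6, 0.1, seed = 30)
  sw <- small_world_indices(net, null_config(n_null = 20, seed = 31))
  expect_equal(sw$sigma, sw$gamma_ratio / sw$lambda_ratio)
  expect_length(sw$null_cp, 20 - sw$n_dropped)
})

test_that("an Erdos-Renyi graph is its own null: gamma and lambda near 1", {
  set.seed(32)
  gammas <- lambdas <- numeric(8)
  for (i in 1:8) {
    net <- random_network(60, 0.2, seed = 400 + i)
    sw <- small_world_indices(net, null_config(n_null = 20, seed = 500 + i))
    gammas[i] <- sw$gamma_ratio
    lambdas[i] <- sw$lambda_ratio
  }
  expect_lt(max(abs(gammas - 1)), 0.35)    # Cp of G(n,p) is noisy at n = 60
  expect_lt(max(abs(lambdas - 1)), 0.1)
  expect_lt(abs(mean(gammas) - 1), 0.1)
})

test_that("null ensemble means are stable across seeds", {
  net <- ring_lattice_network(60, 8, 0.1, seed = 33)
  sw1 <- small_world_indices(net, null_config(n_null = 100, seed = 1))
  sw2 <- small_world_indices(net, null_config(n_null = 100, seed = 2))
  expect_lt(abs(mean(sw1$null_cp) - mean(sw2$null_cp)) /
              mean(sw1$null_cp), 0.05)
  expect_lt(abs(mean(sw1$null_lp) - mean(sw2$null_lp)) /
              mean(sw1$null_lp), 0.05)
})
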