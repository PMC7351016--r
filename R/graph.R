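# Density-thresholded binary networks and their small-world metrics.
#
# Weighted connectivity matrices are converted to undirected binary
# graphs by keeping the strongest |weight| edges up to a target edge
# density ("sparsity degree"), then characterized by the four standard
# small-world metrics, normalized against degree-preserving random
# networks.

#' Binary undirected network
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param density Achieved edge density; computed from the adjacency if
#'   omitted.
#' @return Object of class `binary_network` with elements `adjacency`,
#'   `density`, `n_nodes`, `n_edges`.
#' @export
binary_network <- function(adjacency, density = NULL) {
  A <- as.matrix(adjacency)
  if (nrow(A) != ncol(A)) stopf("adjacency must be square")
  if (!all(A %in% c(0, 1))) stopf("adjacency must be 0/1")
  if (!isTRUE(all.equal(A, t(A)))) stopf("adjacency must be symmetric")
  if (any(diag(A) != 0)) stopf("adjacency must have a zero diagonal")
  storage.mode(A) <- "integer"
  m <- nrow(A)
  n_edges <- sum(A[upper.tri(A)])
  n_pairs <- m * (m - 1) / 2
  structure(list(adjacency = A,
                 density = if (is.null(density)) n_edges / n_pairs else density,
                 n_nodes = m, n_edges = n_edges),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (density %.4f)\n",
              x$n_nodes, x$n_edges, x$density))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      diag = FALSE)
}

igraph_to_network <- function(g) {
  binary_network(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
}

#' Threshold a weighted matrix at a target edge density
#'
#' Ranks the off-diagonal upper-triangle entries by absolute weight,
#' descending, and keeps the top `K = round(density * M(M-1)/2)` as
#' edges (rounding half away from zero). Ties at the cutoff are broken
#' by lexicographic (i, j) order, so the result is deterministic. If the
#' weighted matrix has fewer than K nonzero entries — common for sparse
#' L1 matrices at high target densities — all nonzero-weight edges are
#' kept, the shortfall is recorded, and a warning is issued.
#'
#' @param W A [connectivity_matrix()] or square numeric matrix.
#' @param density Target edge density in `(0, 1]`.
#' @return A [binary_network()]; the achieved density may fall short of
#'   the target, in which case attribute `shortfall` gives the number of
#'   missing edges.
#' @export
binarize_at_density <- function(W, density) {
  if (inherits(W, "connectivity_matrix")) W <- W$weights
  if (!is.matrix(W) || nrow(W) != ncol(W)) stopf("W must be a square matrix")
  if (!is_number(density) || density <= 0 || density > 1)
    stopf("density must lie in (0, 1], got %s", format(density))
  m <- nrow(W)
  n_pairs <- m * (m - 1) / 2
  K <- floor(density * n_pairs + 0.5)   # round half away from zero
  up <- which(upper.tri(W), arr.ind = TRUE)
  w <- abs(W[upper.tri(W)])
  ord <- order(-w, up[, 1], up[, 2])
  n_nonzero <- sum(w > 0)
  keep_n <- min(K, n_nonzero)
  shortfall <- K - keep_n
  if (shortfall > 0)
    warnf("only %d nonzero weights for a target of %d edges (density %.3f); achieved density %.3f",
          n_nonzero, K, density, keep_n / n_pairs)
  keep <- up[ord[seq_len(keep_n)], , drop = FALSE]
  A <- matrix(0L, m, m)
  A[keep] <- 1L
  A <- A + t(A)
  net <- binary_network(A, density = keep_n / n_pairs)
  attr(net, "target_density") <- density
  attr(net, "shortfall") <- shortfall
  net
}

#' Mean clustering coefficient
#'
#' Average over nodes of `2 t_i / (k_i (k_i - 1))`, where `t_i` is the
#' number of triangles through node i and `k_i` its degree; nodes with
#' degree < 2 contribute 0. A measure of local segregation.
#'
#' @param net A [binary_network()].
#' @return A number in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net)
  cp <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  if (is.nan(cp)) 0 else cp
}

#' Characteristic path length
#'
#' Mean shortest-path hop count over all unordered pairs that are
#' reachable from one another; the number of unreachable pairs is
#' attached as attribute `unreachable_pairs`. Errors if the graph has no
#' reachable pairs at all.
#'
#' @param net A [binary_network()].
#' @return Mean hop count (`>= 1`), with attribute `unreachable_pairs`.
#' @export
characteristic_path_length <- function(net) {
  d <- igraph::distances(as_igraph(net))
  du <- d[upper.tri(d)]
  reachable <- is.finite(du)
  if (!any(reachable)) stopf("no reachable pairs: the graph has no edges")
  structure(mean(du[reachable]),
            unreachable_pairs = sum(!reachable))
}

#' Global efficiency
#'
#' Mean over all unordered pairs of the inverse shortest path length,
#' with 1/Inf = 0 for unreachable pairs; well defined on disconnected
#' graphs and 0 on an edgeless one.
#'
#' @param net A [binary_network()].
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  if (net$n_nodes < 2) return(0)
  d <- igraph::distances(as_igraph(net))
  du <- d[upper.tri(d)]
  mean(ifelse(is.finite(du) & du > 0, 1 / du, 0))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by
#' the node's neighbors; nodes with degree < 2 contribute 0. Captures
#' the fault tolerance of local wiring.
#'
#' @param net A [binary_network()].
#' @return A number in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  A <- net$adjacency
  m <- net$n_nodes
  vals <- vapply(seq_len(m), function(i) {
    nb <- which(A[i, ] == 1L)
    if (length(nb) < 2) return(0)
    global_efficiency(binary_network(A[nb, nb, drop = FALSE]))
  }, numeric(1))
  mean(vals)
}

#' All four small-world metrics at once
#'
#' @param net A [binary_network()].
#' @return Named list: `cp`, `lp`, `eg`, `eloc`, `unreachable_pairs`.
#' @export
metric_set <- function(net) {
  lp <- characteristic_path_length(net)
  list(cp = clustering_coefficient(net),
       lp = as.numeric(lp),
       eg = global_efficiency(net),
       eloc = local_efficiency(net),
       unreachable_pairs = attr(lp, "unreachable_pairs"))
}

#' Null-model ensemble configuration
#'
#' @param n_null Number of degree-preserving random networks.
#' @param swaps_per_edge Attempted double-edge swaps per edge when
#'   rewiring.
#' @param seed Integer seed for the ensemble.
#' @return Object of class `null_config`.
#' @export
null_config <- function(n_null = 100L, swaps_per_edge = 10L, seed = 1L) {
  if (!is_count(n_null)) stopf("n_null must be a positive integer")
  if (!is_count(swaps_per_edge)) stopf("swaps_per_edge must be a positive integer")
  structure(list(n_null = as.integer(n_null),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_config")
}

#' Degree-preserving random rewiring
#'
#' Attempts `swaps_per_edge * n_edges` double-edge swaps, each rejected
#' if it would create a self-loop or a duplicate edge, so the degree
#' sequence is preserved exactly. If no swap could be applied (e.g. a
#' triangle, where every candidate swap is invalid) the input is
#' returned unchanged with a warning.
#'
#' @param net A [binary_network()] with at least 2 edges.
#' @param cfg A [null_config()]; only `swaps_per_edge` and `seed` are
#'   used.
#' @return A rewired [binary_network()] with the same degree sequence.
#' @export
rewire_degree_preserving <- function(net, cfg = null_config()) {
  if (net$n_edges < 2) stopf("need at least 2 edges to rewire")
  g <- as_igraph(net)
  g2 <- with_seed(cfg$seed,
    igraph::rewire(g, igraph::keeping_degseq(
      loops = FALSE, niter = cfg$swaps_per_edge * net$n_edges)))
  out <- igraph_to_network(g2)
  if (identical(out$adjacency, net$adjacency))
    warnf("rewiring left the graph unchanged (no valid swap was applied)")
  out
}

#' Small-world indices against a degree-preserving null ensemble
#'
#' Builds `cfg$n_null` rewired networks with the same degree sequence
#' and computes `gamma_ratio = Cp(G) / mean Cp(null)`, `lambda_ratio =
#' Lp(G) / mean Lp(null)` and `sigma = gamma_ratio / lambda_ratio`. A
#' network is conventionally called small-world when `gamma_ratio > 1`
#' with `lambda_ratio ~ 1`, equivalently `sigma > 1`. Nulls on which the
#' path length is undefined are dropped and counted; more than 20%
#' dropped is an error.
#'
#' @param net A [binary_network()].
#' @param cfg A [null_config()].
#' @return Object of class `small_world_indices`: `gamma_ratio`,
#'   `lambda_ratio`, `sigma`, the real `cp`/`lp`, per-null vectors
#'   `null_cp`/`null_lp`, and `n_dropped`.
#' @export
small_world_indices <- function(net, cfg = null_config()) {
  cp <- clustering_coefficient(net)
  lp <- as.numeric(characteristic_path_length(net))
  null_cp <- numeric(cfg$n_null)
  null_lp <- numeric(cfg$n_null)
  for (k in seq_len(cfg$n_null)) {
    nk <- suppressWarnings(rewire_degree_preserving(
      net, null_config(n_null = 1L, swaps_per_edge = cfg$swaps_per_edge,
                       seed = derive_seed(cfg$seed, k))))
    null_cp[k] <- clustering_coefficient(nk)
    null_lp[k] <- tryCatch(as.numeric(characteristic_path_length(nk)),
                           error = function(e) NA_real_)
  }
  ok <- !is.na(null_lp)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.2 * cfg$n_null)
    stopf("path length undefined on %d of %d null networks", n_dropped,
          cfg$n_null)
  gamma_ratio <- cp / mean(null_cp[ok])
  lambda_ratio <- lp / mean(null_lp[ok])
  structure(list(gamma_ratio = gamma_ratio, lambda_ratio = lambda_ratio,
                 sigma = gamma_ratio / lambda_ratio,
                 cp = cp, lp = lp,
                 null_cp = null_cp[ok], null_lp = null_lp[ok],
                 n_dropped = n_dropped),
            class = "small_world_indices")
}

#' @export
print.small_world_indices <- function(x, ...) {
  cat(sprintf("<small_world_indices> gamma = %.3f, lambda = %.3f, sigma = %.3f (%d nulls%s)\n",
              x$gamma_ratio, x$lambda_ratio, x$sigma, length(x$null_cp),
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  invisible(x)
}

#' Ring lattice with random shortcuts (Watts-Strogatz graph)
#'
#' Each node starts connected to its `n_neighbors` nearest ring
#' neighbors; every edge is then rewired to a random endpoint with
#' probability `p_rewire`. The classic test bed for small-world
#' behavior: high clustering from the lattice, short paths from the few
#' shortcuts.
#'
#' @param n_nodes Number of nodes.
#' @param n_neighbors Even lattice degree (neighbors per node before
#'   rewiring).
#' @param p_rewire Per-edge rewiring probability.
#' @param seed Integer seed.
#' @return A [binary_network()].
#' @export
ring_lattice_network <- function(n_nodes = 90, n_neighbors = 10,
                                 p_rewire = 0.05, seed = NULL) {
  if (n_neighbors %% 2 != 0) stopf("n_neighbors must be even")
  g <- with_seed(seed,
    igraph::sample_smallworld(1, n_nodes, n_neighbors / 2, p_rewire))
  g <- igraph::simplify(g)
  igraph_to_network(g)
}

#' Uniform (Erdős–Rényi) random network at a given density
#'
#' @param n_nodes Number of nodes.
#' @param density Edge density; the edge count is fixed at
#'   `round(density * n(n-1)/2)`.
#' @param seed Integer seed.
#' @return A [binary_network()].
#' @export
random_network <- function(n_nodes, density, seed = NULL) {
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  m <- floor(density * n_pairs + 0.5)
  g <- with_seed(seed, igraph::sample_gnm(n_nodes, m))
  igraph_to_network(g)
}
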