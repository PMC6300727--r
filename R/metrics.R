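# Weighted graph-topology kernel.
#
# All metrics operate on symmetric non-negative weight matrices (a
# `connectome` or a plain matrix) and treat zero weights as absent edges.
# Path lengths use the reciprocal-weight map (length of an edge = 1/weight),
# the standard convention for connectivity-strength matrices: stronger
# connections are shorter.

as_weight_matrix <- function(G) {
  if (is_connectome(G)) return(conn_weights(G))
  if (is.matrix(G) && is.numeric(G)) {
    if (nrow(G) != ncol(G)) stop("weight matrix must be square", call. = FALSE)
    if (any(G < 0)) stop("weights must be non-negative", call. = FALSE)
    return(G)
  }
  stop("expected a connectome or numeric matrix", call. = FALSE)
}

#' Weighted shortest path lengths
#'
#' All-pairs shortest path lengths under the reciprocal-weight length map:
#' each edge of weight w contributes length 1/w, and the length of a path is
#' the sum of its edge lengths. `Inf` encodes disconnected pairs.
#'
#' @param G a [connectome()] or symmetric non-negative weight matrix.
#' @return N x N matrix of shortest path lengths (zero diagonal, symmetric).
#' @export
shortest_path_lengths <- function(G) {
  W <- as_weight_matrix(G)
  len <- ifelse(W > 0, 1 / W, Inf)
  diag(len) <- 0
  L <- fw_all_pairs(len)
  dimnames(L) <- dimnames(W)
  L
}

#' Global efficiency
#'
#' The capacity of a network for parallel information transfer: the mean of
#' inverse shortest path lengths over all ordered node pairs,
#' `E_glob = (1/(N(N-1))) * sum_{i != j} 1/L_ij`, with `1/Inf = 0` for
#' disconnected pairs. Equals the mean of the nodal efficiencies. For
#' weights in `[0, 1]` it lies in `[0, 1]`; a complete unit-weight graph
#' scores 1 and an edgeless graph 0.
#'
#' @inheritParams shortest_path_lengths
#' @param L optional precomputed result of [shortest_path_lengths()].
#' @return scalar efficiency.
#' @export
global_efficiency <- function(G, L = NULL) {
  if (is.null(L)) L <- shortest_path_lengths(G)
  n <- nrow(L)
  if (n < 2) return(0)
  inv <- 1 / L
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' How readily each node exchanges information with the rest of the network:
#' `E_i = (1/(N-1)) * sum_{j != i} 1/L_ij`. An isolated node scores 0; every
#' node of a complete unit-weight graph scores 1.
#'
#' @inheritParams global_efficiency
#' @return named numeric vector, one efficiency per node.
#' @export
nodal_efficiency <- function(G, L = NULL) {
  if (is.null(L)) L <- shortest_path_lengths(G)
  inv <- 1 / L
  diag(inv) <- 0
  rowSums(inv) / (nrow(L) - 1)
}

#' Weighted nodal degree centrality
#'
#' `D_i = sum_j w_ij`, the total connection strength incident to each node.
#'
#' @inheritParams shortest_path_lengths
#' @return named numeric vector of weighted degrees.
#' @export
nodal_degree <- function(G) {
  W <- as_weight_matrix(G)
  rowSums(W)
}

#' Local efficiency
#'
#' Fault tolerance of local circuits: the mean over nodes of the global
#' efficiency of each node's neighbourhood subgraph (the subgraph induced on
#' the neighbours of i, retaining their mutual weights; node i itself is
#' excluded). Nodes with fewer than two neighbours contribute 0.
#'
#' @inheritParams shortest_path_lengths
#' @return scalar local efficiency.
#' @export
local_efficiency <- function(G) {
  W <- as_weight_matrix(G)
  local_efficiency_kernel(W)
}

#' Weighted clustering coefficient
#'
#' Onnela geometric-mean form: with weights rescaled by the network maximum,
#' the intensity of each triangle is the geometric mean of its three edge
#' weights, and the per-node coefficient is the total triangle intensity at
#' that node divided by `k_i (k_i - 1)` (binary degree k). The network
#' coefficient is the mean over all nodes; nodes with binary degree < 2
#' contribute 0. A unit-weight triangle scores 1, a tree 0.
#'
#' @inheritParams shortest_path_lengths
#' @return scalar clustering coefficient.
#' @export
weighted_clustering <- function(G) {
  W <- as_weight_matrix(G)
  mx <- max(W)
  if (mx == 0) return(0)
  A <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  tri <- diag(A %*% A %*% A)          # 2 x triangle intensity per node
  c_i <- ifelse(k > 1, tri / (k * (k - 1)), 0)
  mean(c_i)
}

#' Weighted characteristic path length
#'
#' Mean shortest path length over connected ordered node pairs; disconnected
#' pairs are excluded from the average (disconnection is instead penalised
#' through the efficiency metrics, where `1/Inf = 0`).
#'
#' @inheritParams global_efficiency
#' @return scalar path length.
#' @export
characteristic_path_length <- function(G, L = NULL) {
  if (is.null(L)) L <- shortest_path_lengths(G)
  off <- L[row(L) != col(L)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) stop("graph is fully disconnected: no finite path lengths",
                             call. = FALSE)
  mean(fin)
}

edge_list <- function(W) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2], w = W[idx])
}

#' Degree-preserving weighted null network
#'
#' Randomises topology by repeated double-edge swaps (two edges (u,v), (x,y)
#' are replaced by (u,x), (v,y) when neither new edge exists), which exactly
#' preserves node count, edge count and the binary degree sequence. Weights
#' travel with the swapped edges, so the weight multiset is preserved too.
#' Proposals that would create self-loops or multi-edges are rejected; if the
#' proposal budget (`100 * target swaps`) is exhausted before the target
#' number of swaps is achieved, a warning is emitted and the current state
#' returned.
#'
#' @inheritParams shortest_path_lengths
#' @param n_swaps_per_edge attempted successful swaps per edge (default 10).
#' @param seed optional integer seed; when supplied the caller's RNG stream
#'   is left untouched.
#' @return a rewired object of the same type as `G`.
#' @export
rewire_null <- function(G, n_swaps_per_edge = 10, seed = NULL) {
  W <- as_weight_matrix(G)
  el <- edge_list(W)
  m <- length(el$w)
  if (m < 4) stop("need at least 4 edges to rewire", call. = FALSE)
  target <- ceiling(n_swaps_per_edge * m)
  res <- with_preserved_seed(seed,
    ms_rewire(el$i, el$j, el$w, nrow(W), target, 100L * target))
  if (res$n_done < target) {
    warning(sprintf("rewiring achieved %d of %d swaps before the proposal limit",
                    res$n_done, target))
  }
  Wn <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  Wn[cbind(res$i, res$j)] <- res$w
  Wn[cbind(res$j, res$i)] <- res$w
  if (is_connectome(G)) connectome(Wn, modality(G)) else Wn
}

#' Small-worldness against a degree-preserving null ensemble
#'
#' `SW = (C_net / C_rand) / (L_net / L_rand)`, where `C` is the weighted
#' clustering coefficient, `L` the weighted characteristic path length, and
#' the `rand` terms are means over an ensemble of degree-preserving rewired
#' null networks (default 100, matching common practice). A small-world
#' network combines the short paths of a random graph with much higher
#' clustering, giving `SW > 1`.
#'
#' @inheritParams rewire_null
#' @param n_null number of null networks (default 100).
#' @return scalar small-worldness ratio, with the four ingredients attached
#'   as attribute `"components"`.
#' @export
small_worldness <- function(G, n_null = 100, n_swaps_per_edge = 10,
                            seed = NULL) {
  W <- as_weight_matrix(G)
  C_net <- weighted_clustering(W)
  L_net <- characteristic_path_length(W)
  stats_null <- with_preserved_seed(seed, {
    vapply(seq_len(n_null), function(b) {
      Wb <- rewire_null(W, n_swaps_per_edge = n_swaps_per_edge)
      c(weighted_clustering(Wb), characteristic_path_length(Wb))
    }, numeric(2))
  })
  C_rand <- mean(stats_null[1, ])
  L_rand <- mean(stats_null[2, ])
  sw <- (C_net / C_rand) / (L_net / L_rand)
  attr(sw, "components") <- c(C_net = C_net, L_net = L_net,
                              C_rand = C_rand, L_rand = L_rand)
  sw
}

#' All global metrics of one network
#'
#' Convenience wrapper returning the global-wise metrics of a single
#' weighted network as a one-row tibble.
#'
#' @inheritParams small_worldness
#' @param sw whether to also compute small-worldness (slow; off by default).
#' @return tibble with columns `e_glob`, `e_loc`, `c_w`, `l_w` (and `sw_w`).
#' @export
global_metrics <- function(G, sw = FALSE, n_null = 100, seed = NULL) {
  L <- shortest_path_lengths(G)
  out <- tibble::tibble(
    e_glob = global_efficiency(G, L = L),
    e_loc = local_efficiency(G),
    c_w = weighted_clustering(G),
    l_w = characteristic_path_length(G, L = L)
  )
  if (sw) out$sw_w <- as.numeric(small_worldness(G, n_null = n_null, seed = seed))
  out
}
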