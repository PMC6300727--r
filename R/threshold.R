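# Proportional cost thresholding and composite (cost-integrated) metrics.
#
# The cost of a network is its edge density: the number of retained edges
# over all N(N-1)/2 possible edges. Proportional thresholding retains the
# k = round(cost * N(N-1)/2) strongest edges with their original weights,
# making network comparisons across subjects fair at matched wiring cost.

#' Candidate cost grid
#'
#' The uniform grid of candidate cost thresholds over which connectome
#' properties are evaluated, by default `0.01 <= cost <= 0.40` in steps of
#' `0.01`.
#'
#' @param from,to,step grid limits and step.
#' @return numeric vector of costs.
#' @export
cost_grid <- function(from = 0.01, to = 0.40, step = 0.01) {
  stopifnot(from > 0, to <= 1, step > 0, to > from)
  round(seq(from, to, by = step), 10)
}

#' Threshold a connectome at a proportional cost
#'
#' Retains the `k = round(cost * N(N-1)/2)` largest-weight edges (original
#' weights kept) and zeroes all others. Ties at the cutoff weight are broken
#' deterministically: the edge earlier in (i, j) lexicographic order (upper
#' triangle, i < j) is kept.
#'
#' @inheritParams shortest_path_lengths
#' @param cost fraction of possible edges to retain, in (0, 1].
#' @return thresholded object of the same type as `G`.
#' @export
apply_cost <- function(G, cost) {
  if (!is.numeric(cost) || length(cost) != 1 || cost <= 0 || cost > 1) {
    stop("`cost` must be a single value in (0, 1]", call. = FALSE)
  }
  W <- as_weight_matrix(G)
  n <- nrow(W)
  k <- round(cost * n * (n - 1) / 2)
  if (k == 0) stop("cost ", cost, " retains zero edges at N = ", n, call. = FALSE)
  el <- edge_list(W)
  m <- length(el$w)
  if (m > k) {
    keep <- order(-el$w, el$i, el$j)[seq_len(k)]
    Wt <- matrix(0, n, n, dimnames = dimnames(W))
    Wt[cbind(el$i[keep], el$j[keep])] <- el$w[keep]
    Wt <- Wt + t(Wt)
  } else {
    Wt <- W
  }
  if (is_connectome(G)) connectome(Wt, modality(G)) else Wt
}

#' Connectedness summary of a network
#'
#' Reports whether the binary topology forms a single connected component
#' and the fraction of nodes in the largest component (an empty graph scores
#' `1/N`: each node is its own singleton component).
#'
#' @inheritParams shortest_path_lengths
#' @return tibble with columns `connected` and `frac_largest`.
#' @export
connectedness <- function(G) {
  W <- as_weight_matrix(G)
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(g)
  frac <- max(comp$csize) / nrow(W)
  tibble::tibble(connected = comp$no == 1, frac_largest = frac)
}

#' Default cost-range selection criteria
#'
#' The structural criteria require, at every candidate cost, that each
#' subject's network is sparse but fully connected, that the mean number of
#' binary connections per node exceeds `log(N)`, and that small-worldness
#' exceeds 1.2. The functional criteria require that at least 80% of nodes
#' sit in the largest component for at least 95% of subjects, the same mean
#' degree condition, and small-worldness above 1.
#'
#' @param modality `"SC"` or `"FC"`.
#' @return list of criterion settings.
#' @export
default_criteria <- function(modality = c("SC", "FC")) {
  modality <- match.arg(modality)
  if (modality == "SC") {
    list(sw_min = 1.2, require_all_connected = TRUE,
         frac_nodes = 1, frac_subjects = 1)
  } else {
    list(sw_min = 1, require_all_connected = FALSE,
         frac_nodes = 0.80, frac_subjects = 0.95)
  }
}

#' Select the analysed cost range for a cohort of connectomes
#'
#' Evaluates the modality's criteria (see [default_criteria()]) at each
#' candidate cost across all subjects and returns the maximal contiguous run
#' of passing costs. Connectedness and mean degree are evaluated per subject;
#' small-worldness is evaluated on the cohort's group-mean connectome at each
#' cost with a reduced null ensemble (`n_null`, default 20) to keep the sweep
#' affordable — full-ensemble small-worldness is reserved for reported
#' metrics.
#'
#' @param cohort list of [connectome()]s of one modality, all the same size.
#' @param modality `"SC"` or `"FC"`.
#' @param costs candidate [cost_grid()].
#' @param criteria criterion settings; defaults to [default_criteria()]. An
#'   optional `reference_window = c(lo, hi)` entry makes the function warn
#'   when the selected range differs from that reference (useful when a
#'   published window for comparable data is known).
#' @param n_null nulls per cost for the small-worldness screen.
#' @param seed RNG seed for the null ensembles.
#' @return object of class `cost_range`: list with `costs` (selected grid),
#'   `modality`, and `detail` (per-cost criterion tibble).
#' @export
select_cost_range <- function(cohort, modality = c("SC", "FC"),
                              costs = cost_grid(), criteria = NULL,
                              n_null = 20, seed = NULL) {
  modality <- match.arg(modality)
  if (length(cohort) == 0) stop("`cohort` is empty", call. = FALSE)
  ns <- vapply(cohort, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("all connectomes must have the same node count",
                                    call. = FALSE)
  n <- ns[1]
  if (is.null(criteria)) criteria <- default_criteria(modality)
  mean_W <- Reduce(`+`, lapply(cohort, as_weight_matrix)) / length(cohort)

  # order each subject's edges once; thresholds are nested so each cost is a
  # prefix of the sorted edge list (same tie rule as apply_cost)
  sorted_edges <- lapply(cohort, function(G) {
    el <- edge_list(as_weight_matrix(G))
    o <- order(-el$w, el$i, el$j)
    list(i = el$i[o], j = el$j[o], m = length(o))
  })

  detail <- purrr::map_dfr(seq_along(costs), function(ci) {
    cost <- costs[ci]
    k <- round(cost * n * (n - 1) / 2)
    if (k == 0) {
      return(tibble::tibble(cost = cost, connected_ok = FALSE, degree_ok = FALSE,
                            sw = NA_real_, sw_ok = FALSE, pass = FALSE,
                            first_fail = "no edges retained"))
    }
    per_subj <- vapply(sorted_edges, function(el) {
      kk <- min(k, el$m)
      g <- igraph::graph_from_edgelist(cbind(el$i[seq_len(kk)],
                                             el$j[seq_len(kk)]),
                                       directed = FALSE)
      if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
      comp <- igraph::components(g)
      c(connected = comp$no == 1, frac = max(comp$csize) / n,
        mean_deg = 2 * kk / n)
    }, numeric(3))
    if (criteria$require_all_connected) {
      connected_ok <- all(per_subj["connected", ] == 1)
    } else {
      connected_ok <- mean(per_subj["frac", ] >= criteria$frac_nodes) >=
        criteria$frac_subjects
    }
    degree_ok <- all(per_subj["mean_deg", ] > log(n))
    sw_seed <- if (is.null(seed)) NULL else derive_seed(seed, ci)
    sw <- tryCatch(
      as.numeric(small_worldness(apply_cost(mean_W, cost), n_null = n_null,
                                 seed = sw_seed)),
      error = function(e) NA_real_)
    sw_ok <- !is.na(sw) && sw > criteria$sw_min
    pass <- connected_ok && degree_ok && sw_ok
    first_fail <- if (pass) NA_character_
      else if (!connected_ok) "connectedness"
      else if (!degree_ok) "mean degree <= log(N)"
      else sprintf("small-worldness <= %g", criteria$sw_min)
    tibble::tibble(cost = cost, connected_ok = connected_ok,
                   degree_ok = degree_ok, sw = sw, sw_ok = sw_ok,
                   pass = pass, first_fail = first_fail)
  })

  runs <- rle(detail$pass)
  if (!any(runs$values)) {
    msg <- paste(sprintf("cost %.2f: %s", detail$cost, detail$first_fail),
                 collapse = "\n  ")
    stop("no candidate cost satisfies the ", modality, " criteria:\n  ", msg,
         call. = FALSE)
  }
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  best <- which(runs$values)[which.max(runs$lengths[runs$values])]
  sel <- detail$cost[starts[best]:ends[best]]
  if (!is.null(criteria$reference_window)) {
    ref <- criteria$reference_window
    if (abs(min(sel) - ref[1]) > 1e-9 || abs(max(sel) - ref[2]) > 1e-9) {
      warning(sprintf(
        "selected %s range %.2f-%.2f differs from the reference window %.2f-%.2f",
        modality, min(sel), max(sel), ref[1], ref[2]))
    }
  }
  structure(list(costs = sel, modality = modality, detail = detail),
            class = "cost_range")
}

#' @export
print.cost_range <- function(x, ...) {
  cat(sprintf("<cost_range> %s: %.2f-%.2f (%d costs)\n", x$modality,
              min(x$costs), max(x$costs), length(x$costs)))
  invisible(x)
}

#' Integrate a per-cost metric over a cost range
#'
#' The composite measure of a metric is its integral across the selected
#' cost range (trapezoidal rule on the uniform cost grid), yielding one
#' threshold-robust value in units of metric x cost.
#'
#' @param values numeric vector, the metric evaluated at each cost.
#' @param costs numeric vector of costs (same length, >= 2, increasing).
#' @return scalar integral.
#' @export
composite <- function(values, costs) {
  if (inherits(costs, "cost_range")) costs <- costs$costs
  if (length(values) != length(costs)) {
    stop("`values` and `costs` must have equal length", call. = FALSE)
  }
  if (length(costs) < 2) stop("need at least 2 costs to integrate", call. = FALSE)
  if (any(diff(costs) <= 0)) stop("`costs` must be strictly increasing", call. = FALSE)
  sum(diff(costs) * (head(values, -1) + values[-1]) / 2)
}

#' Composite global and nodal metrics for one subject
#'
#' Evaluates global efficiency, local efficiency, nodal degree centrality
#' and nodal efficiency of one connectome at every cost in the range, then
#' integrates each across the range.
#'
#' @inheritParams shortest_path_lengths
#' @param costs selected cost range ([select_cost_range()] result or numeric
#'   vector, >= 2 costs).
#' @param include_local whether to compute (slower) local efficiency.
#' @return list with `global` (one-row tibble of composite `e_glob`
#'   and, when requested, `e_loc`) and `nodal` (tibble with one row per node:
#'   composite `degree` and `e_nodal`).
#' @export
subject_composites <- function(G, costs, include_local = TRUE) {
  if (inherits(costs, "cost_range")) costs <- costs$costs
  W <- as_weight_matrix(G)
  n <- nrow(W)
  labs <- colnames(W)
  if (is.null(labs)) labs <- default_node_labels(n)
  # sort edges once; each cost keeps a prefix (same tie rule as apply_cost)
  el <- edge_list(W)
  o <- order(-el$w, el$i, el$j)
  ei <- el$i[o]; ej <- el$j[o]; ew <- el$w[o]
  m <- length(ew)
  eg <- numeric(length(costs)); elc <- numeric(length(costs))
  deg <- matrix(0, n, length(costs)); en <- matrix(0, n, length(costs))
  for (ci in seq_along(costs)) {
    k <- round(costs[ci] * n * (n - 1) / 2)
    if (k == 0) stop("cost ", costs[ci], " retains zero edges", call. = FALSE)
    kk <- min(k, m)
    Wt <- matrix(0, n, n)
    idx <- seq_len(kk)
    Wt[cbind(ei[idx], ej[idx])] <- ew[idx]
    Wt <- Wt + t(Wt)
    L <- shortest_path_lengths(Wt)
    eg[ci] <- global_efficiency(Wt, L = L)
    if (include_local) elc[ci] <- local_efficiency(Wt)
    deg[, ci] <- rowSums(Wt)
    en[, ci] <- nodal_efficiency(Wt, L = L)
  }
  glob <- tibble::tibble(e_glob = composite(eg, costs))
  if (include_local) glob$e_loc <- composite(elc, costs)
  nodal <- tibble::tibble(
    node = labs,
    degree = apply(deg, 1, composite, costs = costs),
    e_nodal = apply(en, 1, composite, costs = costs)
  )
  list(global = glob, nodal = nodal)
}

#' Global-efficiency profile across a cost sweep
#'
#' Evaluates [global_efficiency()] of the thresholded network at each cost
#' in one pass (compiled kernel; thresholding and tie-breaking identical to
#' [apply_cost()]). Useful for dense sweeps and simulation studies.
#'
#' @inheritParams shortest_path_lengths
#' @param costs numeric vector of costs in (0, 1].
#' @return numeric vector of global efficiencies, one per cost.
#' @export
efficiency_cost_profile <- function(G, costs) {
  if (inherits(costs, "cost_range")) costs <- costs$costs
  W <- as_weight_matrix(G)
  eglob_cost_profile(W, costs)
}
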