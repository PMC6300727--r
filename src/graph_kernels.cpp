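#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest path lengths by Floyd-Warshall on a dense length matrix.
// Input: N x N matrix of edge lengths (R_PosInf where no edge, 0 on the
// diagonal). Returns the matrix of shortest path lengths (R_PosInf encodes
// disconnection).
// [[Rcpp::export]]
NumericMatrix fw_all_pairs(NumericMatrix len) {
  int n = len.nrow();
  if (len.ncol() != n) stop("length matrix must be square");
  NumericMatrix d = clone(len);
  for (int i = 0; i < n; ++i) d(i, i) = 0.0;
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d(i, k);
      if (dik == R_PosInf) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  }
  return d;
}

// Degree-preserving double-edge swaps (Maslov-Sneppen) on an undirected
// weighted edge list. Edge endpoints are 1-based node indices with ei < ej.
// Weights travel with the swapped half-edges, so the weight multiset and the
// binary degree sequence are both preserved. Uses R's RNG (honours set.seed).
// Returns a list with the rewired edge list and the achieved swap count.
// [[Rcpp::export]]
List ms_rewire(IntegerVector ei, IntegerVector ej, NumericVector w,
               int n_nodes, int n_swaps, int max_tries) {
  int m = ei.size();
  if (ej.size() != m || w.size() != m) stop("edge list components disagree");
  IntegerVector a = clone(ei), b = clone(ej);
  NumericVector wt = clone(w);
  // adjacency lookup for O(1) existence tests
  std::vector<unsigned char> adj((size_t)n_nodes * n_nodes, 0);
  for (int e = 0; e < m; ++e) {
    adj[(size_t)(a[e] - 1) * n_nodes + (b[e] - 1)] = 1;
    adj[(size_t)(b[e] - 1) * n_nodes + (a[e] - 1)] = 1;
  }
  int done = 0, tries = 0;
  while (done < n_swaps && tries < max_tries) {
    ++tries;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int u = a[e1], v = b[e1], x = a[e2], y = b[e2];
    // randomly orient the second edge so both swap variants are proposed
    if (unif_rand() < 0.5) { int t = x; x = y; y = t; }
    // proposed new edges: (u,x) and (v,y)
    if (u == x || v == y || u == y || v == x) continue; // self-loop or shared node
    if (adj[(size_t)(u - 1) * n_nodes + (x - 1)]) continue;
    if (adj[(size_t)(v - 1) * n_nodes + (y - 1)]) continue;
    adj[(size_t)(u - 1) * n_nodes + (v - 1)] = 0;
    adj[(size_t)(v - 1) * n_nodes + (u - 1)] = 0;
    adj[(size_t)(x - 1) * n_nodes + (y - 1)] = 0;
    adj[(size_t)(y - 1) * n_nodes + (x - 1)] = 0;
    a[e1] = u; b[e1] = x;
    a[e2] = v; b[e2] = y;
    adj[(size_t)(u - 1) * n_nodes + (x - 1)] = 1;
    adj[(size_t)(x - 1) * n_nodes + (u - 1)] = 1;
    adj[(size_t)(v - 1) * n_nodes + (y - 1)] = 1;
    adj[(size_t)(y - 1) * n_nodes + (v - 1)] = 1;
    ++done;
  }
  return List::create(_["i"] = a, _["j"] = b, _["w"] = wt,
                      _["n_done"] = done, _["n_tries"] = tries);
}

// Global-efficiency profile across proportional cost thresholds.
// For each cost, retains the k = round(cost * N(N-1)/2) largest-weight
// edges (ties broken by (i,j) lexicographic order), runs Floyd-Warshall on
// reciprocal-weight lengths, and returns E_glob = mean of 1/L over ordered
// pairs. One call per subject keeps cost sweeps cheap.
// [[Rcpp::export]]
NumericVector eglob_cost_profile(NumericMatrix W, NumericVector costs) {
  int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  struct Edge { int i, j; double w; };
  std::vector<Edge> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W(i, j) > 0) edges.push_back({i, j, W(i, j)});
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w > b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  int m = (int)edges.size();
  int nc = costs.size();
  NumericVector out(nc);
  std::vector<double> d((size_t)n * n);
  for (int c = 0; c < nc; ++c) {
    int k = (int)Rf_fround(costs[c] * n * (n - 1) / 2.0, 0);
    if (k < 1) stop("cost retains zero edges");
    if (k > m) k = m;
    std::fill(d.begin(), d.end(), R_PosInf);
    for (int i = 0; i < n; ++i) d[(size_t)i * n + i] = 0.0;
    for (int e = 0; e < k; ++e) {
      double len = 1.0 / edges[e].w;
      d[(size_t)edges[e].i * n + edges[e].j] = len;
      d[(size_t)edges[e].j * n + edges[e].i] = len;
    }
    for (int kk = 0; kk < n; ++kk)
      for (int i = 0; i < n; ++i) {
        double dik = d[(size_t)i * n + kk];
        if (dik == R_PosInf) continue;
        for (int j = 0; j < n; ++j) {
          double alt = dik + d[(size_t)kk * n + j];
          if (alt < d[(size_t)i * n + j]) d[(size_t)i * n + j] = alt;
        }
      }
    double s = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j && d[(size_t)i * n + j] != R_PosInf)
          s += 1.0 / d[(size_t)i * n + j];
    out[c] = s / ((double)n * (n - 1));
  }
  return out;
}

// Local efficiency: mean over nodes of the global efficiency of each
// node's neighbourhood subgraph (mutual weights retained, reciprocal-weight
// lengths). Nodes with fewer than two neighbours contribute 0.
// [[Rcpp::export]]
double local_efficiency_kernel(NumericMatrix W) {
  int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  std::vector<int> nb;
  std::vector<double> d;
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) if (W(i, j) > 0) nb.push_back(j);
    int m = (int)nb.size();
    if (m < 2) continue;
    d.assign((size_t)m * m, R_PosInf);
    for (int a = 0; a < m; ++a) {
      d[(size_t)a * m + a] = 0.0;
      for (int b = a + 1; b < m; ++b) {
        double w = W(nb[a], nb[b]);
        if (w > 0) d[(size_t)a * m + b] = d[(size_t)b * m + a] = 1.0 / w;
      }
    }
    for (int k = 0; k < m; ++k)
      for (int a = 0; a < m; ++a) {
        double dak = d[(size_t)a * m + k];
        if (dak == R_PosInf) continue;
        for (int b = 0; b < m; ++b) {
          double alt = dak + d[(size_t)k * m + b];
          if (alt < d[(size_t)a * m + b]) d[(size_t)a * m + b] = alt;
        }
      }
    double s = 0.0;
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        if (a != b && d[(size_t)a * m + b] != R_PosInf)
          s += 1.0 / d[(size_t)a * m + b];
    total += s / ((double)m * (m - 1));
  }
  return total / n;
}
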