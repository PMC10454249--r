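#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weight -> edge length. conv: 0 = 1/w, 1 = 1 - w, 2 = -log(w).
// Non-positive weights mean "no edge" (infinite length).
static inline double edge_len(double w, int conv) {
  if (!(w > 0.0)) return R_PosInf;
  switch (conv) {
    case 0: return 1.0 / w;
    case 1: return 1.0 - w;
    default: return -std::log(w);
  }
}

// Floyd-Warshall on a column-major n x n length buffer, in place.
static void fw_inplace(std::vector<double>& d, int n) {
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < n; ++j) {
      double dkj = d[k + j * n];
      if (!R_FINITE(dkj)) continue;
      for (int i = 0; i < n; ++i) {
        double alt = d[i + k * n] + dkj;
        if (alt < d[i + j * n]) d[i + j * n] = alt;
      }
    }
  }
}

static void lengths_from_weights(const double* w, int n, int conv,
                                 std::vector<double>& d) {
  d.resize((size_t)n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      d[i + j * n] = (i == j) ? 0.0 : edge_len(w[i + j * n], conv);
}

// Mean inverse shortest-path length over ordered pairs (1/Inf = 0).
static double efficiency_from_dist(const std::vector<double>& d, int n) {
  if (n < 2) return 0.0;
  double acc = 0.0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (i != j && R_FINITE(d[i + j * n])) acc += 1.0 / d[i + j * n];
  return acc / ((double)n * (n - 1));
}

// [[Rcpp::export]]
NumericMatrix cpp_distances(NumericMatrix w, int conv) {
  int n = w.nrow();
  std::vector<double> d;
  lengths_from_weights(w.begin(), n, conv, d);
  fw_inplace(d, n);
  NumericMatrix out(n, n);
  std::copy(d.begin(), d.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
double cpp_global_efficiency(NumericMatrix w, int conv) {
  int n = w.nrow();
  std::vector<double> d;
  lengths_from_weights(w.begin(), n, conv, d);
  fw_inplace(d, n);
  return efficiency_from_dist(d, n);
}

// Per-node local efficiency: global efficiency of the subnetwork induced on
// each node's neighbors (original weights kept); nodes with < 2 neighbors
// contribute 0.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(NumericMatrix w, int conv) {
  int n = w.nrow();
  NumericVector out(n);
  std::vector<int> nb;
  std::vector<double> sub;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && w(i, j) > 0.0) nb.push_back(j);
    int m = (int)nb.size();
    if (m < 2) { out[i] = 0.0; continue; }
    sub.resize((size_t)m * m);
    for (int b = 0; b < m; ++b)
      for (int a = 0; a < m; ++a)
        sub[a + b * m] = (a == b) ? 0.0 : edge_len(w(nb[a], nb[b]), conv);
    fw_inplace(sub, m);
    out[i] = efficiency_from_dist(sub, m);
  }
  return out;
}
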