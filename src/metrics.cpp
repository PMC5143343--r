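#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// In-place Floyd-Warshall on a dense column-major length buffer.
// Lengths are non-negative, R_PosInf where no direct step exists; the
// diagonal is forced to zero. Inner loop runs down column j so memory
// access stays contiguous.
static void fw_inplace(double* d, int n) {
  for (int i = 0; i < n; ++i) d[i + (size_t)n * i] = 0.0;
  for (int k = 0; k < n; ++k) {
    const double* dk = d + (size_t)n * k;   // column k: d(i, k)
    for (int j = 0; j < n; ++j) {
      const double dkj = d[k + (size_t)n * j];
      if (!R_FINITE(dkj)) continue;
      double* dj = d + (size_t)n * j;       // column j: d(i, j)
      for (int i = 0; i < n; ++i) {
        double alt = dk[i] + dkj;
        if (alt < dj[i]) dj[i] = alt;
      }
    }
  }
}

static double efficiency_from_dist(const double* d, int n) {
  if (n < 2) return 0.0;
  double acc = 0.0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      double dij = d[i + (size_t)n * j];
      if (R_FINITE(dij) && dij > 0) acc += 1.0 / dij;
    }
  return acc / ((double)n * (n - 1));
}

// All-pairs shortest paths by Floyd-Warshall on a dense length matrix.
// [[Rcpp::export]]
NumericMatrix fw_apsp(NumericMatrix len) {
  int n = len.nrow();
  if (len.ncol() != n) stop("length matrix must be square");
  NumericMatrix d = clone(len);
  fw_inplace(d.begin(), n);
  return d;
}

// Mean over ordered node pairs (i != j) of 1/d(i,j), disconnected pairs
// contributing zero: the efficiency of the network whose direct step
// lengths are `len`.
// [[Rcpp::export]]
double pairwise_efficiency(NumericMatrix len) {
  int n = len.nrow();
  if (len.ncol() != n) stop("length matrix must be square");
  if (n < 2) return 0.0;
  std::vector<double> d(len.begin(), len.end());
  fw_inplace(d.data(), n);
  return efficiency_from_dist(d.data(), n);
}

// Local efficiency: mean over nodes of the efficiency of the subgraph
// induced by each node's neighbors (nodes with < 2 neighbors contribute 0).
// `len` is the full direct-step length matrix; neighbors are the finite
// off-diagonal entries of row i.
// [[Rcpp::export]]
double local_efficiency_cpp(NumericMatrix len) {
  int n = len.nrow();
  if (len.ncol() != n) stop("length matrix must be square");
  if (n == 0) return 0.0;
  std::vector<int> nb(n);
  std::vector<double> sub((size_t)n * n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (R_FINITE(len(i, j)) && len(i, j) > 0) nb[k++] = j;
    }
    if (k < 2) continue;
    for (int b = 0; b < k; ++b)
      for (int a = 0; a < k; ++a)
        sub[a + (size_t)k * b] = len(nb[a], nb[b]);
    fw_inplace(sub.data(), k);
    acc += efficiency_from_dist(sub.data(), k);
  }
  return acc / n;
}
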