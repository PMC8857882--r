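#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Classic dynamic-time-warping dynamic program with absolute-difference
// local cost and the symmetric step pattern {(1,0),(0,1),(1,1)}, no window
// constraint. Returns the accumulated cost at the end point and the length
// (number of cells) of one optimal warping path, recovered by backtracking
// with a deterministic tie-break (diagonal, then up, then left).
// [[Rcpp::export]]
List dtw_pair_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n < 1 || m < 1) stop("DTW requires non-empty sequences");
  const double *pa = a.begin(), *pb = b.begin();
  std::vector<double> D((size_t)n * m);   // row-major: D[i*m + j]
  D[0] = std::fabs(pa[0] - pb[0]);
  for (int j = 1; j < m; ++j) D[j] = D[j - 1] + std::fabs(pa[0] - pb[j]);
  for (int i = 1; i < n; ++i) {
    double *row = &D[(size_t)i * m], *prev = &D[(size_t)(i - 1) * m];
    const double ai = pa[i];
    row[0] = prev[0] + std::fabs(ai - pb[0]);
    for (int j = 1; j < m; ++j) {
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (row[j - 1] < best) best = row[j - 1];
      row[j] = best + std::fabs(ai - pb[j]);
    }
  }
  // backtrack one optimal path; prefer diagonal, then up, then left
  int i = n - 1, j = m - 1;
  double len = 1;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double diag = D[(size_t)(i - 1) * m + j - 1];
      double up = D[(size_t)(i - 1) * m + j];
      double left = D[(size_t)i * m + j - 1];
      if (diag <= up && diag <= left) { --i; --j; }
      else if (up <= left) { --i; }
      else { --j; }
    } else if (i > 0) {
      --i;
    } else {
      --j;
    }
    len += 1;
  }
  return List::create(_["cost"] = D[(size_t)n * m - 1],
                      _["pathLength"] = len);
}
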