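#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Distance to the k-th nearest neighbour (Euclidean, self excluded) for every
// row of x. Brute force O(n^2 d) with a partial selection per row; n here is
// at most a few thousand trials (or 1e4 in calibration runs), so this beats
// tree structures that pay heavy constants at d <= 4.
// [[Rcpp::export]]
NumericVector knn_kth_distance_cpp(NumericMatrix x, int k) {
  const int n = x.nrow(), d = x.ncol();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  // row-major copy: the inner loop then walks contiguous memory
  std::vector<double> xr((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i) xr[(size_t)i * d + j] = x(i, j);
  NumericVector out(n);
  std::vector<double> d2((size_t)n - 1);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xr[(size_t)i * d];
    size_t m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double* xj = &xr[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = xi[c] - xj[c];
        s += diff * diff;
      }
      d2[m++] = s;
    }
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    out[i] = std::sqrt(d2[k - 1]);
  }
  return out;
}
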