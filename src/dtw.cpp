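#include <Rcpp.h>
using namespace Rcpp;

// Accumulated cost of the optimal monotone warping alignment between two
// 1-D sequences under absolute-difference local cost:
//   DS(i,j) = |a_i - b_j| + min(DS(i-1,j), DS(i-1,j-1), DS(i,j-1)),
//   DS(1,1) = |a_1 - b_1|.
// Returns DS(n, m). Only two rows are kept.
// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<double> prev(m), cur(m);
  prev[0] = std::abs(a[0] - b[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::abs(a[0] - b[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::abs(a[i] - b[0]);
    for (int j = 1; j < m; ++j) {
      double best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = best + std::abs(a[i] - b[j]);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
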