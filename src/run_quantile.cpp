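#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Centered moving percentile with edge truncation.
//
// Window for index i (0-based) is [max(0, i - half), min(n - 1, i + half)].
// The window is kept as a sorted buffer updated incrementally; the
// percentile uses R's type-7 (linear interpolation) definition so results
// match stats::quantile() on each window exactly.
// [[Rcpp::export]]
NumericVector run_quantile_cpp(NumericVector x, int half, double q) {
  const int n = x.size();
  if (half < 1) stop("`half` must be at least 1");
  if (q < 0.0 || q > 1.0) stop("`q` must be in [0, 1]");
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(2 * half + 2);

  int lo = 0, hi = std::min(n - 1, half);  // current window [lo, hi]
  for (int j = lo; j <= hi; ++j) {
    buf.insert(std::lower_bound(buf.begin(), buf.end(), x[j]), x[j]);
  }
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      int new_hi = std::min(n - 1, i + half);
      int new_lo = std::max(0, i - half);
      if (new_hi > hi) {
        double v = x[new_hi];
        buf.insert(std::lower_bound(buf.begin(), buf.end(), v), v);
        hi = new_hi;
      }
      if (new_lo > lo) {
        double v = x[lo];
        buf.erase(std::lower_bound(buf.begin(), buf.end(), v));
        lo = new_lo;
      }
    }
    const int m = (int) buf.size();
    const double h = q * (m - 1);
    const int k = (int) std::floor(h);
    if (k + 1 < m) {
      out[i] = buf[k] + (h - k) * (buf[k + 1] - buf[k]);
    } else {
      out[i] = buf[m - 1];
    }
  }
  return out;
}
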