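#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Sliding-window percentile with truncated (not padded) edge windows.
// For a window of length w the span around frame i is
// [i - floor((w-1)/2), i + (w-1) - floor((w-1)/2)], clipped to the trace.
// The window is maintained as a sorted vector (one insert + one erase per
// frame), and the quantile of each window replicates
// stats::quantile(type = 7) bit-for-bit: index = 1 + (n-1)*p,
// q = (1-h)*x[lo] + h*x[hi].
// [[Rcpp::export(name = ".running_percentile_cpp")]]
NumericVector running_percentile_cpp(NumericVector x, int window, double prob) {
  const int n = x.size();
  if (window < 1) stop("`window` must be >= 1");
  if (prob < 0.0 || prob > 1.0) stop("`prob` must be in [0, 1]");
  const int hl = (window - 1) / 2;
  const int hr = (window - 1) - hl;
  NumericVector out(n);
  std::vector<double> win;
  win.reserve(std::min(window, n) + 1);

  // initial window for i = 0: [0, min(n-1, hr)]
  for (int j = 0; j <= std::min(n - 1, hr); ++j) win.push_back(x[j]);
  std::sort(win.begin(), win.end());

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      const int add = i + hr;            // entering sample
      if (add <= n - 1) {
        win.insert(std::upper_bound(win.begin(), win.end(), x[add]), x[add]);
      }
      const int drop = i - hl - 1;       // leaving sample
      if (drop >= 0) {
        win.erase(std::lower_bound(win.begin(), win.end(), x[drop]));
      }
    }
    const int m = (int)win.size();
    const double index = 1.0 + (m - 1) * prob;  // 1-based, as in stats::quantile
    const int jlo = (int)std::floor(index);
    const double h = index - jlo;
    if (h > 0.0 && jlo < m) {
      out[i] = (1.0 - h) * win[jlo - 1] + h * win[jlo];
    } else {
      out[i] = win[jlo - 1];
    }
  }
  return out;
}
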