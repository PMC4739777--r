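#include <Rcpp.h>
#include <set>
using namespace Rcpp;

// Sliding "mean of the lowest 50%" baseline, one value per frame.
//
// For frame i the window is the inclusive frame range [i-h, i+h], truncated
// at the recording edges; with m frames in the window the baseline is the
// mean of the k = max(1, floor(m/2)) smallest values. A two-multiset
// partition (the k smallest in `low`, the rest in `high`) with a running
// sum of `low` gives O(F log W) per trace instead of a per-frame sort.

class LowerHalfTracker {
  std::multiset<double> low, high;
  double low_sum = 0.0;

 public:
  void add(double x) {
    if (!low.empty() && x <= *low.rbegin()) {
      low.insert(x);
      low_sum += x;
    } else {
      high.insert(x);
    }
  }
  void remove(double x) {
    auto it = low.find(x);
    if (it != low.end()) {
      low_sum -= x;
      low.erase(it);
    } else {
      high.erase(high.find(x));
    }
  }
  void rebalance(size_t k) {
    while (low.size() > k) {
      auto it = std::prev(low.end());
      double v = *it;
      low.erase(it);
      low_sum -= v;
      high.insert(v);
    }
    while (low.size() < k && !high.empty()) {
      auto it = high.begin();
      double v = *it;
      high.erase(it);
      low.insert(v);
      low_sum += v;
    }
  }
  double mean_low() const { return low_sum / (double)low.size(); }
};

// [[Rcpp::export(name = ".sliding_lower_mean")]]
NumericMatrix sliding_lower_mean(NumericMatrix f, int half_window) {
  int n = f.nrow(), F = f.ncol(), h = half_window;
  NumericMatrix out(n, F);
  for (int r = 0; r < n; ++r) {
    LowerHalfTracker trk;
    int lo = 0, hi = -1;  // current window [lo, hi] inclusive
    for (int j = 0; j <= std::min(h, F - 1); ++j) {
      trk.add(f(r, j));
      hi = j;
    }
    for (int i = 0; i < F; ++i) {
      int want_lo = std::max(0, i - h), want_hi = std::min(F - 1, i + h);
      while (hi < want_hi) trk.add(f(r, ++hi));
      while (lo < want_lo) trk.remove(f(r, lo++));
      int m = want_hi - want_lo + 1;
      size_t k = std::max(1, m / 2);
      trk.rebalance(k);
      out(r, i) = trk.mean_low();
    }
  }
  return out;
}
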