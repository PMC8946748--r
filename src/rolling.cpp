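#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Centered sliding-window peak-to-peak (max - min) with window w samples
// (forced odd). Edge windows shrink. Monotonic-deque algorithm, O(n).
// [[Rcpp::export(name = ".rolling_p2p")]]
NumericVector rolling_p2p(NumericVector x, int w) {
  int n = x.size();
  if (w < 1) w = 1;
  if (w % 2 == 0) ++w;
  int h = w / 2;
  NumericVector out(n);
  std::deque<int> qmax, qmin;
  int right = -1;
  for (int i = 0; i < n; ++i) {
    int lo = i - h, hi = std::min(n - 1, i + h);
    while (right < hi) {
      ++right;
      while (!qmax.empty() && x[qmax.back()] <= x[right]) qmax.pop_back();
      qmax.push_back(right);
      while (!qmin.empty() && x[qmin.back()] >= x[right]) qmin.pop_back();
      qmin.push_back(right);
    }
    while (!qmax.empty() && qmax.front() < lo) qmax.pop_front();
    while (!qmin.empty() && qmin.front() < lo) qmin.pop_front();
    out[i] = x[qmax.front()] - x[qmin.front()];
  }
  return out;
}
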