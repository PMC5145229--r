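#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Rolling extrema over all length-k windows, left-aligned: result[i] covers
// x[i .. i+k-1]. Monotonic-deque algorithm, O(n) regardless of k.

static NumericVector roll_extremum(const NumericVector& x, int k, bool maximum) {
  const int n = x.size();
  if (k < 1 || k > n) stop("window length out of range");
  NumericVector out(n - k + 1);
  std::deque<int> q; // indices, values monotone
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    while (!q.empty() &&
           (maximum ? x[q.back()] <= v : x[q.back()] >= v)) q.pop_back();
    q.push_back(i);
    if (q.front() <= i - k) q.pop_front();
    if (i >= k - 1) out[i - k + 1] = x[q.front()];
  }
  return out;
}

// [[Rcpp::export(name = ".rollMaxLeft")]]
NumericVector rollMaxLeft(NumericVector x, int k) {
  return roll_extremum(x, k, true);
}

// [[Rcpp::export(name = ".rollMinLeft")]]
NumericVector rollMinLeft(NumericVector x, int k) {
  return roll_extremum(x, k, false);
}
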