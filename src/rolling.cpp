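#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Trailing-window extrema over [t-k+1, t], truncated at the series start.
// NA cells poison every window that covers them (handled by the R wrappers
// via a separate NA-run mask; here NA input yields NA output directly).

// [[Rcpp::export]]
NumericVector cpp_run_max(NumericVector x, int k) {
  const int n = x.size();
  NumericVector out(n);
  std::deque<int> q; // indices, values decreasing
  for (int t = 0; t < n; ++t) {
    if (NumericVector::is_na(x[t])) {
      // restart: the window max is undefined until the NA leaves the window
      q.clear();
      out[t] = NA_REAL;
      continue;
    }
    while (!q.empty() && x[q.back()] <= x[t]) q.pop_back();
    q.push_back(t);
    while (!q.empty() && q.front() <= t - k) q.pop_front();
    out[t] = q.empty() ? NA_REAL : x[q.front()];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_run_min(NumericVector x, int k) {
  const int n = x.size();
  NumericVector out(n);
  std::deque<int> q;
  for (int t = 0; t < n; ++t) {
    if (NumericVector::is_na(x[t])) {
      q.clear();
      out[t] = NA_REAL;
      continue;
    }
    while (!q.empty() && x[q.back()] >= x[t]) q.pop_back();
    q.push_back(t);
    while (!q.empty() && q.front() <= t - k) q.pop_front();
    out[t] = q.empty() ? NA_REAL : x[q.front()];
  }
  return out;
}

// Trailing moving average over [t-k+1, t], truncated at the start.
// NA propagates to every window containing it.

// [[Rcpp::export]]
NumericVector cpp_run_mean(NumericVector x, int k) {
  const int n = x.size();
  NumericVector out(n);
  long double s = 0.0;
  // number of NA cells inside the current window
  int na_in = 0;
  for (int t = 0; t < n; ++t) {
    bool na_t = NumericVector::is_na(x[t]);
    if (na_t) ++na_in; else s += x[t];
    if (t >= k) {
      bool na_old = NumericVector::is_na(x[t - k]);
      if (na_old) --na_in; else s -= x[t - k];
    }
    int len = std::min(t + 1, k);
    out[t] = na_in > 0 ? NA_REAL : (double)(s / len);
  }
  return out;
}
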