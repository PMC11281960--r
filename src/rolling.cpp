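#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Centered moving window, truncated (shrinking) at the record edges.
// Window length L: half-widths hl = (L-1)/2 to the left, hr = L-1-hl to
// the right, so an even L extends one sample further to the right.
// Median of an even-sized window is the mean of the central pair.

static inline double sorted_median(const std::vector<double>& buf) {
  const size_t m = buf.size();
  if (m % 2 == 1) return buf[m / 2];
  // long double mirrors R's mean() for the central pair
  long double s = (long double)buf[m / 2 - 1] + (long double)buf[m / 2];
  return (double)(s / 2.0L);
}

// [[Rcpp::export(name = ".roll_median_trunc")]]
NumericVector roll_median_trunc(NumericVector x, int L) {
  const R_xlen_t n = x.size();
  if (n == 0) stop("empty signal");
  if (L < 1) stop("window length must be >= 1");
  const R_xlen_t hl = (L - 1) / 2;
  const R_xlen_t hr = (R_xlen_t)L - 1 - hl;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve((size_t)std::min((R_xlen_t)L, n));
  R_xlen_t lo = 0, hi = -1; // current window [lo, hi]
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t a = std::max((R_xlen_t)0, i - hl);
    R_xlen_t b = std::min(n - 1, i + hr);
    while (hi < b) {
      ++hi;
      double v = x[hi];
      if (!R_finite(v)) stop("non-finite sample at index %td", (ptrdiff_t)(hi + 1));
      buf.insert(std::upper_bound(buf.begin(), buf.end(), v), v);
    }
    while (lo < a) {
      double v = x[lo];
      std::vector<double>::iterator it =
        std::lower_bound(buf.begin(), buf.end(), v);
      buf.erase(it);
      ++lo;
    }
    out[i] = sorted_median(buf);
  }
  return out;
}

// Population standard deviation (divide by the window count) over the same
// centered truncated windows.  The signal is centered on its global mean and
// long-double prefix sums are used so the two-pass brute-force value is
// reproduced to ~1e-15.
// [[Rcpp::export(name = ".roll_sd_trunc")]]
NumericVector roll_sd_trunc(NumericVector x, int L) {
  const R_xlen_t n = x.size();
  if (n == 0) stop("empty signal");
  if (L < 1) stop("window length must be >= 1");
  const R_xlen_t hl = (L - 1) / 2;
  const R_xlen_t hr = (R_xlen_t)L - 1 - hl;

  long double gs = 0.0L;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!R_finite(x[i])) stop("non-finite sample at index %td", (ptrdiff_t)(i + 1));
    gs += x[i];
  }
  const long double gm = gs / (long double)n;

  std::vector<long double> p1((size_t)n + 1, 0.0L), p2((size_t)n + 1, 0.0L);
  for (R_xlen_t i = 0; i < n; ++i) {
    long double y = (long double)x[i] - gm;
    p1[(size_t)i + 1] = p1[(size_t)i] + y;
    p2[(size_t)i + 1] = p2[(size_t)i] + y * y;
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t a = std::max((R_xlen_t)0, i - hl);
    R_xlen_t b = std::min(n - 1, i + hr);
    long double m = (long double)(b - a + 1);
    long double s1 = p1[(size_t)b + 1] - p1[(size_t)a];
    long double s2 = p2[(size_t)b + 1] - p2[(size_t)a];
    long double var = s2 / m - (s1 / m) * (s1 / m);
    if (var < 0.0L) var = 0.0L;
    out[i] = (double)sqrtl(var);
  }
  return out;
}

// Topographic prominence of candidate peaks: for each candidate index,
// walk outward to the nearest strictly higher sample (or record edge),
// tracking the minimum on each side; prominence = peak value minus the
// higher of the two side minima.
// [[Rcpp::export(name = ".peak_prominence")]]
NumericVector peak_prominence(NumericVector x, IntegerVector idx1) {
  const R_xlen_t n = x.size();
  NumericVector out(idx1.size());
  for (R_xlen_t c = 0; c < idx1.size(); ++c) {
    R_xlen_t i = (R_xlen_t)idx1[c] - 1; // 1-based -> 0-based
    if (i < 0 || i >= n) stop("candidate index outside the record");
    double amp = x[i];
    double lmin = amp, rmin = amp;
    for (R_xlen_t j = i - 1; j >= 0; --j) {
      if (x[j] > amp) break;
      if (x[j] < lmin) lmin = x[j];
    }
    for (R_xlen_t j = i + 1; j < n; ++j) {
      if (x[j] > amp) break;
      if (x[j] < rmin) rmin = x[j];
    }
    out[c] = amp - std::max(lmin, rmin);
  }
  return out;
}
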