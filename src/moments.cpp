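#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Raw bivariate moments of lagged count pairs, accumulated in long double.
// For each lag tau_k the pairs are (x[i], y[i + tau_k]) over all start bins
// fully inside the trace. `mask` selects which (m, n) orders to compute
// (orders beyond those needed for the delta-method variances are skipped).

// [[Rcpp::export(name = ".lagged_moments_cpp")]]
List lagged_moments_cpp(NumericVector x, NumericVector y,
                        IntegerVector tau_k, int max_m, int max_n,
                        LogicalMatrix mask) {
  const R_xlen_t L = x.size();
  if (y.size() != L) stop("channel traces must have equal length");
  const int nm = max_m + 1, nn = max_n + 1;
  List out(tau_k.size());
  std::vector<long double> acc((size_t) nm * nn);
  std::vector<double> pa(nm), pb(nn);

  for (int t = 0; t < tau_k.size(); ++t) {
    const R_xlen_t k = tau_k[t];
    if (k < 0 || k >= L) stop("lag outside trace");
    const R_xlen_t nd = L - k;
    std::fill(acc.begin(), acc.end(), 0.0L);
    // dim traces are mostly zeros and ones: a zero on either axis kills
    // every mixed power, and unit counts contribute 1 to every power, so
    // those frequent pairs reduce to simple tallies
    long long ones_row = 0, ones_col = 0, ones_both = 0;
    for (R_xlen_t i = 0; i < nd; ++i) {
      const double a = x[i], b = y[i + k];
      if (a <= 1.0 && b <= 1.0) {
        if (a == 1.0) { if (b == 1.0) ++ones_both; else ++ones_col; }
        else if (b == 1.0) ++ones_row;
        continue;
      }
      pa[0] = 1.0;
      for (int m = 1; m < nm; ++m) pa[m] = pa[m - 1] * a;
      pb[0] = 1.0;
      for (int n = 1; n < nn; ++n) pb[n] = pb[n - 1] * b;
      if (a == 0.0) {
        for (int n = 1; n < nn; ++n) acc[n] += pb[n];
      } else if (b == 0.0) {
        for (int m = 1; m < nm; ++m) acc[(size_t) m * nn] += pa[m];
      } else {
        for (int m = 1; m < nm; ++m) acc[(size_t) m * nn] += pa[m];
        for (int n = 1; n < nn; ++n) acc[n] += pb[n];
        for (int m = 1; m < nm; ++m) {
          const double pam = pa[m];
          for (int n = 1; n < nn; ++n)
            if (mask(m, n)) acc[(size_t) m * nn + n] += pam * pb[n];
        }
      }
    }
    // fold the tallies of pairs made only of zeros and ones
    for (int n = 1; n < nn; ++n) acc[n] += (long double) (ones_row + ones_both);
    for (int m = 1; m < nm; ++m) acc[(size_t) m * nn] += (long double) (ones_col + ones_both);
    for (int m = 1; m < nm; ++m)
      for (int n = 1; n < nn; ++n)
        if (mask(m, n)) acc[(size_t) m * nn + n] += (long double) ones_both;
    NumericMatrix M(nm, nn);
    for (int m = 0; m < nm; ++m)
      for (int n = 0; n < nn; ++n)
        M(m, n) = mask(m, n) ? (double) (acc[(size_t) m * nn + n] / nd)
                             : NA_REAL;
    M(0, 0) = 1.0;
    out[t] = M;
  }
  return out;
}
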