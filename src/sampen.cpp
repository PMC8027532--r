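#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.
// Both template lengths (m and m+1) are drawn from the same N - m starting
// positions so the counts are comparable; self-matches (i == j) are excluded
// and matching uses the Chebyshev (max-coordinate) distance with a strict
// inequality (< r).
// Returns c(A, B): A = number of m-length matching pairs, B = number of
// (m+1)-length matching pairs.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // template count, identical for both lengths
  const double *p = x.begin();
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    const double *pi = p + i;
    const double x0 = pi[0];
    for (int j = i + 1; j < nt; ++j) {
      const double *pj = p + j;
      double d = x0 - pj[0];
      if (d >= r || d <= -r) continue;
      bool match = true;
      for (int k = 1; k < m; ++k) {
        d = pi[k] - pj[k];
        if (d >= r || d <= -r) { match = false; break; }
      }
      if (match) {
        A += 1.0;
        d = pi[m] - pj[m];
        if (d < r && d > -r) B += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
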