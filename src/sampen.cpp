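#include <Rcpp.h>
#include <cmath>

// Match counting for sample entropy, Richman-Moorman convention:
// templates of length m and m+1 are both taken from the first N - m
// starting positions, pairs are unordered (i < j), self-matches excluded,
// Chebyshev distance with inclusive tolerance (<= r). Under this
// convention a constant input gives A == B and SampEn exactly 0.
//
// [[Rcpp::export]]
Rcpp::List sampen_counts_cpp(Rcpp::NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of template starting positions
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      // extension to length m + 1 stays in bounds: i + m <= n - 1
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("B") = B);
}
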