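#include <Rcpp.h>
#include <cmath>
#include <vector>

// Template-matching counts shared by sample entropy and approximate entropy.
// Chebyshev (max-norm) distance between length-m subsequences.

// [[Rcpp::export]]
Rcpp::NumericVector sampen_counts_cpp(Rcpp::NumericVector x, int m, double r) {
  // Richman–Moorman counts: both template lengths use the same N - m
  // starting points; self-matches excluded; unordered pairs counted once.
  const int n = x.size();
  const int nt = n - m;  // templates of length m (and m+1) indexed 0..nt-1
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm <= r) A += 1.0;
      }
    }
  }
  return Rcpp::NumericVector::create(B, A);
}

static double phi_m(const Rcpp::NumericVector& x, int m, double r) {
  // Pincus correlation sum: self-matches included, so every count >= 1.
  const int n = x.size();
  const int nt = n - m + 1;
  std::vector<double> cnt(nt, 1.0);  // self-match
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) { cnt[i] += 1.0; cnt[j] += 1.0; }
    }
  }
  double s = 0.0;
  for (int i = 0; i < nt; ++i) s += std::log(cnt[i] / nt);
  return s / nt;
}

// [[Rcpp::export]]
double apen_cpp(Rcpp::NumericVector x, int m, double r) {
  return phi_m(x, m, r) - phi_m(x, m + 1, r);
}
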