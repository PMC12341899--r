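#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pincus approximate entropy: ApEn(m, r, N) = Phi^m(r) - Phi^(m+1)(r),
// Phi^m(r) = mean_i log( C_i^m(r) ), with C_i^m the fraction of length-m
// templates within Chebyshev distance r of template i (self-matches
// included, natural logarithm).  O(n^2); the hot loop of the analysis.
static double phi(const NumericVector& x, const int mm, const double r) {
  const int nm = x.size() - mm + 1;
  double s = 0.0;
  for (int i = 0; i < nm; ++i) {
    int cnt = 0;
    for (int j = 0; j < nm; ++j) {
      bool ok = true;
      for (int k = 0; k < mm; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (ok) ++cnt;
    }
    s += std::log(static_cast<double>(cnt) / nm);
  }
  return s / nm;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  if (x.size() < m + 2) stop("series too short for embedding length m");
  return phi(x, m, r) - phi(x, m + 1, r);
}
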