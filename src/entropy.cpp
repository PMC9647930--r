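#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy SampEn(m, r) with Chebyshev
// distance and self-matches excluded. Returns the number of template pairs
// matching at length m (B) and at length m + 1 (A); SampEn = -log(A / B).
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  const double* p = &x[0];
  unsigned long long A = 0, B = 0;
  int nTemp = n - m;  // templates of length m+1 exist for i in [0, n-m-1]
  for (int i = 0; i < nTemp - 1; ++i) {
    for (int j = i + 1; j < nTemp; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(p[i + k] - p[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      ++B;
      if (std::fabs(p[i + m] - p[j + m]) <= r) ++A;
    }
  }
  return NumericVector::create(_["A"] = (double)A, _["B"] = (double)B);
}

// Non-overlapping window means (coarse-graining for multiscale entropy).
// [[Rcpp::export]]
NumericVector cpp_coarse_grain(NumericVector x, int scale) {
  int n = x.size() / scale;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0;
    for (int k = 0; k < scale; ++k) s += x[i * scale + k];
    out[i] = s / scale;
  }
  return out;
}

// Total variation (line length) of a trace: sum of |successive differences|.
// [[Rcpp::export]]
double cpp_line_length(NumericVector x) {
  double s = 0;
  for (int i = 1; i < x.size(); ++i) s += std::fabs(x[i] - x[i - 1]);
  return s;
}
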