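#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Plug-in transfer entropy TE(x -> y) in nats from pre-binned symbol
// sequences (values 0..k-1), history length 1, one-step horizon:
//   TE = sum p(y+, y, x) * log[ p(y+ | y, x) / p(y+ | y) ]
// computed from joint counts; non-negative up to floating error, clipped at 0.
static double te_from_bins(const int* xb, const int* yb, int n, int k) {
  std::vector<double> nabc(k * k * k, 0.0);   // (y+, y, x)
  std::vector<double> nab(k * k, 0.0);        // (y+, y)
  std::vector<double> nbc(k * k, 0.0);        // (y, x)
  std::vector<double> nb(k, 0.0);             // (y)
  int N = n - 1;
  for (int t = 0; t < N; ++t) {
    int a = yb[t + 1], b = yb[t], c = xb[t];
    nabc[(a * k + b) * k + c] += 1;
    nab[a * k + b] += 1;
    nbc[b * k + c] += 1;
    nb[b] += 1;
  }
  double te = 0;
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b)
      for (int c = 0; c < k; ++c) {
        double cnt = nabc[(a * k + b) * k + c];
        if (cnt == 0) continue;
        te += cnt / N * std::log(cnt * nb[b] / (nab[a * k + b] * nbc[b * k + c]));
      }
  return te > 0 ? te : 0;
}

// [[Rcpp::export]]
double cpp_transfer_entropy(IntegerVector xbins, IntegerVector ybins, int k) {
  if (xbins.size() != ybins.size()) stop("series lengths differ");
  if (xbins.size() < 3) stop("series too short for transfer entropy");
  return te_from_bins(&xbins[0], &ybins[0], xbins.size(), k);
}

// All ordered pairs (i -> j), i != j, from a bins matrix (neurons x time).
// [[Rcpp::export]]
NumericMatrix cpp_te_matrix(IntegerMatrix bins, int k) {
  int n = bins.nrow(), T = bins.ncol();
  std::vector<std::vector<int>> rows(n, std::vector<int>(T));
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) rows[i][t] = bins(i, t);
  NumericMatrix te(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) { te(i, j) = 0; continue; }
      te(i, j) = te_from_bins(rows[i].data(), rows[j].data(), T, k);
    }
  return te;
}
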