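#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// False-nearest-neighbor fraction for delay embeddings of dimension
// d = 1..maxDim (Kennel's criterion). For each embedding vector the nearest
// neighbor (Euclidean, self excluded) is found among a strided subset of at
// most maxVectors vectors; the neighbor is false if either
//   (1) the extra (d+1)-th coordinate separates the pair by more than rtol
//       times their distance in d dimensions, or
//   (2) the inflated distance exceeds atol standard deviations of the signal.
// Vectors are restricted to the range where the (d+1)-dimensional embedding
// also exists so both tests use the same point set.
// [[Rcpp::export]]
NumericVector cpp_fnn_fractions(NumericVector x, int delay, int maxDim,
                                double rtol, double atol, int maxVectors) {
  int n = x.size();
  double mean = 0, sd = 0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  for (int i = 0; i < n; ++i) sd += (x[i] - mean) * (x[i] - mean);
  sd = std::sqrt(sd / (n - 1));

  NumericVector frac(maxDim, NA_REAL);
  for (int d = 1; d <= maxDim; ++d) {
    int last = n - d * delay;  // vectors with an extra coordinate available
    if (last < 2) break;
    int stride = last > maxVectors ? (last + maxVectors - 1) / maxVectors : 1;
    std::vector<int> idx;
    for (int i = 0; i < last; i += stride) idx.push_back(i);
    int nv = idx.size();
    if (nv < 2) break;

    int nFalse = 0, nTotal = 0;
    for (int a = 0; a < nv; ++a) {
      int i = idx[a];
      double best = R_PosInf;
      int bestJ = -1;
      for (int b = 0; b < nv; ++b) {
        if (b == a) continue;
        int j = idx[b];
        double dist2 = 0;
        for (int k = 0; k < d; ++k) {
          double diff = x[i + k * delay] - x[j + k * delay];
          dist2 += diff * diff;
          if (dist2 >= best) break;
        }
        if (dist2 < best) { best = dist2; bestJ = j; }
      }
      if (bestJ < 0) continue;
      double rd = std::sqrt(best);
      double extra = std::fabs(x[i + d * delay] - x[bestJ + d * delay]);
      bool isFalse;
      if (rd == 0.0) {
        isFalse = extra > 0.0;
      } else {
        double rdp1 = std::sqrt(best + extra * extra);
        isFalse = (extra / rd > rtol) || (sd > 0 && rdp1 / sd > atol);
      }
      nTotal++;
      if (isFalse) nFalse++;
    }
    frac[d - 1] = nTotal > 0 ? (double)nFalse / nTotal : NA_REAL;
  }
  return frac;
}
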