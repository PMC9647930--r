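#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Rate functions for the gating variables, voltages in mV, rates in 1/ms.
// The linear-over-expm1 terms have a removable singularity at x = 0; they are
// evaluated with the series limit when the argument is small.
static inline double vtrap(double x, double denom) {
  // x / (exp(x / denom) - 1), stable near x = 0 where the limit is denom.
  double y = x / denom;
  if (std::fabs(y) < 1e-7) return denom * (1.0 - y / 2.0);
  return x / std::expm1(y);
}

static inline double alpha_m(double V, double VT) {
  return 0.32 * vtrap(13.0 - V + VT, 4.0);
}
static inline double beta_m(double V, double VT) {
  return 0.28 * vtrap(V - VT - 40.0, 5.0);
}
static inline double alpha_n(double V, double VT) {
  return 0.032 * vtrap(15.0 - V + VT, 5.0);
}
static inline double beta_n(double V, double VT) {
  return 0.5 * std::exp((10.0 - V + VT) / 40.0);
}
static inline double alpha_h(double V, double VT) {
  return 0.128 * std::exp((17.0 - V + VT) / 18.0);
}
static inline double beta_h(double V, double VT) {
  return 4.0 / (1.0 + std::exp((40.0 - V + VT) / 5.0));
}

// [[Rcpp::export]]
NumericVector cpp_gating_steady(double V, double VT) {
  double am = alpha_m(V, VT), bm = beta_m(V, VT);
  double an = alpha_n(V, VT), bn = beta_n(V, VT);
  double ah = alpha_h(V, VT), bh = beta_h(V, VT);
  return NumericVector::create(_["m"] = am / (am + bm),
                               _["n"] = an / (an + bn),
                               _["h"] = ah / (ah + bh));
}

// [[Rcpp::export]]
NumericVector cpp_gating_rates(double V, double VT) {
  return NumericVector::create(
      _["alpha_m"] = alpha_m(V, VT), _["beta_m"] = beta_m(V, VT),
      _["alpha_n"] = alpha_n(V, VT), _["beta_n"] = beta_n(V, VT),
      _["alpha_h"] = alpha_h(V, VT), _["beta_h"] = beta_h(V, VT));
}

// Exponential-Euler integration of the network.
//
// State per neuron: V, m, n, h, gNa, gK. Gating ODEs dy/dt = a(1-y) - b y and
// the conductance relaxations are advanced exactly over each step for frozen
// rates; the voltage equation, linear in V for frozen conductances, is also
// advanced exactly. A spike is recorded on an upward crossing of `vSpike`;
// while V stays at or above the threshold the neuron is refractory and no
// further crossing can occur. Presynaptic spike effects (Tsodyks-Markram
// release, conductance increments on targets) are applied at the end of the
// step in which the spike is detected; synapse state (u, x) is decayed lazily
// with its closed-form exponentials between events.
//
// [[Rcpp::export]]
List cpp_integrate(NumericVector V0, NumericVector m0, NumericVector n0,
                   NumericVector h0, NumericVector gNa0, NumericVector gK0,
                   NumericVector gNaRest, NumericVector gKRest,
                   double gl, double El, double ENa, double EK, double Cm,
                   double tauNa, double tauK, double VT, double vSpike,
                   double dt, int nSteps,
                   IntegerVector edgePre, IntegerVector edgePost,
                   NumericVector edgeIncNa, NumericVector edgeIncK,
                   double U0, double omegaF, double omegaD,
                   bool keepTraces) {
  int n = V0.size();
  int nEdges = edgePre.size();

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> m(m0.begin(), m0.end());
  std::vector<double> nn(n0.begin(), n0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> gNa(gNa0.begin(), gNa0.end());
  std::vector<double> gK(gK0.begin(), gK0.end());

  // CSR-style adjacency over presynaptic neuron.
  std::vector<int> deg(n, 0);
  for (int e = 0; e < nEdges; ++e) deg[edgePre[e]]++;
  std::vector<int> ptr(n + 1, 0);
  for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> eidx(nEdges);
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < nEdges; ++e) eidx[fill[edgePre[e]]++] = e;
  }

  std::vector<double> uS(nEdges, 0.0), xS(nEdges, 1.0);
  std::vector<double> lastEvent(nEdges, 0.0);  // time of last state update (ms)

  NumericMatrix traces(keepTraces ? n : 1, keepTraces ? nSteps : 1);
  std::vector<std::vector<double>> spikes(n);
  std::vector<char> refractory(n, 0);
  for (int i = 0; i < n; ++i) refractory[i] = (V[i] >= vSpike);

  double expNa = std::exp(-dt / tauNa), expK = std::exp(-dt / tauK);

  for (int s = 0; s < nSteps; ++s) {
    double tEnd = (s + 1) * dt;
    std::vector<int> firing;
    for (int i = 0; i < n; ++i) {
      double v = V[i];
      // gating: exact update for frozen rates
      double am = alpha_m(v, VT), bm = beta_m(v, VT);
      double an = alpha_n(v, VT), bn = beta_n(v, VT);
      double ah = alpha_h(v, VT), bh = beta_h(v, VT);
      double minf = am / (am + bm), ninf = an / (an + bn), hinf = ah / (ah + bh);
      double mNew = minf + (m[i] - minf) * std::exp(-dt * (am + bm));
      double nNew = ninf + (nn[i] - ninf) * std::exp(-dt * (an + bn));
      double hNew = hinf + (h[i] - hinf) * std::exp(-dt * (ah + bh));

      // voltage: linear in V for frozen conductances
      double gNaEff = gNa[i] * m[i] * m[i] * m[i] * h[i];
      double gKEff = gK[i] * nn[i] * nn[i] * nn[i] * nn[i];
      double b = (gl + gNaEff + gKEff) / Cm;
      double a = (gl * El + gNaEff * ENa + gKEff * EK) / Cm;
      double vInf = a / b;
      double vNew = vInf + (v - vInf) * std::exp(-b * dt);

      // ligand conductances relax toward rest
      double gNaNew = gNaRest[i] + (gNa[i] - gNaRest[i]) * expNa;
      double gKNew = gKRest[i] + (gK[i] - gKRest[i]) * expK;

      if (!std::isfinite(vNew) || !std::isfinite(gNaNew) || !std::isfinite(gKNew))
        stop("integration failure (non-finite state) at step %d", s + 1);

      if (vNew >= vSpike) {
        if (!refractory[i]) {
          spikes[i].push_back(tEnd);
          refractory[i] = 1;
          firing.push_back(i);
        }
      } else {
        refractory[i] = 0;
      }

      V[i] = vNew; m[i] = mNew; nn[i] = nNew; h[i] = hNew;
      gNa[i] = gNaNew; gK[i] = gKNew;
      if (keepTraces) traces(i, s) = vNew;
    }

    // presynaptic spike effects, applied end of step, additive across sources
    for (size_t f = 0; f < firing.size(); ++f) {
      int i = firing[f];
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
        int e = eidx[k];
        double gap = tEnd - lastEvent[e];
        double u = uS[e] * std::exp(-omegaF * gap);
        double x = 1.0 + (xS[e] - 1.0) * std::exp(-omegaD * gap);
        u = u + U0 * (1.0 - u);
        double r = u * x;
        x = x - r;
        uS[e] = u; xS[e] = x; lastEvent[e] = tEnd;
        int j = edgePost[e];
        gNa[j] += edgeIncNa[e] * r;
        gK[j] += edgeIncK[e] * r;
      }
    }
  }

  List spikeList(n);
  for (int i = 0; i < n; ++i) spikeList[i] = wrap(spikes[i]);

  return List::create(_["traces"] = traces, _["spikes"] = spikeList,
                      _["finalV"] = wrap(V), _["final_m"] = wrap(m),
                      _["final_n"] = wrap(nn), _["final_h"] = wrap(h));
}
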