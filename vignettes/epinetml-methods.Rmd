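---
title: "Modeling and classifying sodium-channel mutation classes in simulated neuronal networks"
author: "epinetml"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and classifying sodium-channel mutation classes in simulated neuronal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`epinetml` simulates small two-dimensional cultures of conductance-based
neurons on a microelectrode-array-like lattice, extracts a fixed panel of 92
electrophysiological features per simulated subject, and classifies subjects
into three genetic classes: healthy, global sodium-channel gain-of-function
(the Dravet-syndrome-type Nav1.1 open-state mutation, `gof`), and
sodium-channel loss-of-function restricted to inhibitory neurons (`lof`).

## Membrane dynamics

Each neuron follows a modified Hodgkin–Huxley membrane equation

$$C_m \frac{dV}{dt} = g_l (E_l - V) + g_{Na}\, m^3 h\, (E_{Na} - V)
  + g_K\, n^4 (E_K - V),$$

with the standard threshold-parameterized rate functions for the gating
fractions $m$, $n$, $h$ (threshold parameter $V_T = -63$ mV). The channel
conductance densities $g_{Na}$ and $g_K$ are themselves dynamic: they relax
exponentially (time constants $\tau_{Na} = \tau_K = 6$ ms) toward resting
values $g_{Na,0} = 100$ and $g_{K,0} = 30$ mS cm$^{-2}$ and are incremented
by synaptic input, so synaptic drive enters as transient conductance, not
injected current. Defaults (per cm$^2$): $C_m = 1\ \mu F$, $g_l = 0.05$ mS,
$E_l = -65$, $E_{Na} = 50$, $E_K = -90$ mV. A spike is recorded on each
upward crossing of $-63$ mV; while the voltage stays at or above threshold
the neuron is refractory, so a sustained depolarization counts once.

Integration is exponential Euler at $dt = 0.1$ ms: each equation is linear
in its own state variable for frozen coefficients and is advanced by its
exact exponential over the step. On the pure leak equation the scheme
reproduces the analytic exponential to machine precision (this is a test).

## Network structure

The default geometry is a 20 × 10 electrode lattice at 10 µm pitch with one
neuron per electrode: 132 excitatory and 68 inhibitory neurons assigned by
random permutation, each with a membrane area drawn uniformly from
10,000–30,000 µm². Directed connections are drawn with the Gaussian
distance profile $p = A\,\exp(-d^2 / 2\,SD^2)$ with amplitude and width from
the presynaptic identity (excitatory: 0.83, 15.5 µm; inhibitory: 0.41,
12 µm); self-connections are excluded. The profile is evaluated with the
negative exponent of a proper Gaussian; a positive sign would diverge with
distance and contradict the stated amplitudes-at-zero.

Synapses follow the Tsodyks–Markram short-term plasticity scheme: between
spikes the docking fraction $u_S$ decays to 0 at $\Omega_f = 3.33$ s$^{-1}$
and the resource fraction $x_S$ recovers to 1 at $\Omega_d = 2$ s$^{-1}$
(closed-form exponentials, evaluated lazily per synapse); on a presynaptic
spike $u_S \leftarrow u_S + U_0(1 - u_S)$ with $U_0 = 0.6$, the release
$r_S = u_S x_S$ is deducted from $x_S$, and each postsynaptic target is
incremented: $g_{Na} \mathrel{+}= w_e r_S R_E$ for excitatory presynaptic
neurons ($w_e = 70$ mS, $R_E = 15.1$), $g_K \mathrel{+}= w_i r_S R_I$ for
inhibitory ones ($w_i = 20$ mS, $R_I = 9$). Transmission delay is zero;
increments from simultaneous spikes accumulate additively at the end of the
step.

## Initial conditions and the area normalization

Starting voltages are uniform on $[E_l, -63]$ mV and gating variables start
at steady state for the initial voltage (avoiding a startup transient
artifact). Initial conductances follow $g = (\eta + 1)\,w\,\hat A$ with
$\eta \sim U(0,1)$ and $\hat A$ the membrane area divided by a
normalization constant. The constant is genuinely open: the raw units
(mS × µm²) are dimensionally inconsistent, so some normalization is forced.
We use 5,000 µm² ($\hat A \in [2, 6]$, initial $g_{Na} \in [140, 840]$
mS cm$^{-2}$). The choice is made on phenotype grounds: the membrane model
self-excites (resting $V_\infty$ crosses $-63$ mV) only when
$g_{Na} \gtrsim 275$ mS cm$^{-2}$, so the initial distribution must straddle
that boundary for a healthy network to show any activity at all. With this
constant every healthy network produces a sparse asynchronous initial volley
(mean rate near 1 Hz), the gain-of-function networks (resting conductance
1680 mS cm$^{-2}$) fire in a sustained, elevated way for the whole second
(about 5 Hz), and loss-of-function networks sit close to healthy — the
qualitative picture of the three classes. Normalizations of 10,000 µm² or
more leave healthy networks exactly silent, which collapses the healthy/lof
contrast to subthreshold trace differences. The constant is exposed in the
configuration (`areaNorm`).

## Disease classes

A mutation affecting a fraction $\phi$ of sodium channels with a fold-change
$\kappa$ of the resting conductance gives
$g_{Na,0}^{\mathrm{eff}} = (1 - \phi)\,g_{Na,0} + \phi\,\kappa\,g_{Na,0}$.
With $\phi = 0.2$: gain-of-function at $\kappa = 80$ gives 1680 mS cm$^{-2}$
(all neurons); loss-of-function at $\kappa = 0$ gives 80 mS cm$^{-2}$
(inhibitory neurons only). The mutation acts on the resting value of the
dynamic conductance; gating kinetics and synaptic dynamics are unchanged.

# The 92-feature panel

Features are organized in five blocks (4 + 6 + 18 + 36 + 28 = 92), each
built from per-neuron scalars summarized over the lattice. The recurring
summary is: mean, max, SD of the per-neuron field, plus mean, max, SD of its
spatial-gradient magnitude (central differences on the electrode lattice,
one-sided at edges, 10 µm spacing).

* **Firing rate (4)**: max rate, max gradient, mean rate, mean gradient.
* **Minimum embedding dimension (6)**: Kennel false-nearest-neighbor
  criterion per neuron (fold-distance threshold 10, 2 SD absolute
  threshold, delay 50 ms = 500 steps, cap 10, acceptance when the false
  fraction drops below 1%). A zero-variance trace has dimension 1. For long
  traces the neighbor search uses a strided subsample of at most 500
  embedding vectors, which bounds the quadratic cost without biasing the
  fraction. When a trace is too short for the full 10-dimension range the
  cap is lowered to what the trace supports.
* **Multiscale entropy (18)**: sample entropy SampEn($m{=}2$,
  $r = 0.2\,\mathrm{SD}$ of the raw trace) of coarse-grained series at
  scales 1–20 steps; per neuron the curve's trapezoid integral, mean and SD,
  each summarized over the lattice. A constant series scores 0; when no
  template match of length $m+1$ exists the Richman–Moorman upper bound
  $-\log\left(2/\left[(N{-}m{-}1)(N{-}m)\right]\right)$ is recorded so the
  panel stays finite.
* **Waveform shape (36)**: events are maximal runs at or above $-63$ mV.
  Paroxysmal depolarization shifts (PDS) are events at least 50% longer
  than the subject-wide mean event duration; interictal spikes (IIS) are
  isolated events (no neighbor within ±50 ms in the same neuron) shorter
  than 50% of it. Per neuron: PDS rate and mean duration, IIS rate and mean
  duration, line length $\sum_t |V_{t+1} - V_t|$, and rectified area
  $\sum_t |V_t| \, dt$ (a signed area of a trace hovering near $-65$ mV
  would be dominated by the offset). The reference duration is per subject:
  with noise-free, largely uniform action potentials a per-neuron reference
  would make the 50% rules degenerate for single-event neurons.
* **Transfer-entropy connectivity (28)**: plug-in transfer entropy between
  all ordered pairs of voltage traces (equal-width 3-level binning per
  trace, history 1, one-step horizon); a directed edge exists above
  5 × 10⁻⁵ nats. Edges take the frequency band of the origin neuron's
  firing rate — alpha [0, 12.5), beta [12.5, 30), gamma [30, 80] Hz — and
  per band (plus "all") the outgoing-degree field is summarized by mean,
  max, total, SD and three gradient summaries.

## Known limitations of the estimators on noise-free signals

Two estimator behaviors deserve explicit mention because they differ from
noisy-data intuition. First, the plug-in transfer entropy has
finite-sample fluctuation of order 10⁻⁴ nats at 10,000 samples whenever the
target trace visits several bins; the 5 × 10⁻⁵ threshold therefore behaves
as a sparsifier on quiet traces rather than a calibrated significance level
(on time-shuffled surrogate pairs against healthy-network targets about
85% — not all — fall below it). Second, directionality: for a
deterministic periodic driver and a smooth follower, the follower's
synaptic-bump level is a phase readout of the driver, so the backward
estimate can exceed the forward one; the package's tests assert threshold
crossings under coupling rather than a direction inequality. Both behaviors
are properties of low-order plug-in estimators on noise-free signals, not
implementation artifacts.

# Classification

Features are screened by Welch two-sample t-tests between each pair of
classes; a feature enters the model set when any pairwise p-value is below
0.02 (a feature constant within both groups of a pair scores p = 1 for that
pair). Retained features are z-scored with training-split statistics (test
data reuse the stored statistics; fitting on all data would leak). The five
classifiers:

* `nn` — multilayer perceptron, three identical hidden layers as wide as
  the input, rectified-linear activations, softmax output, cross-entropy
  loss, Adam optimizer, 800 epochs at batch size 80 (in-package
  implementation);
* `svm` — radial-basis support vector machine, cost 0.2 (`e1071`);
* `gnb` — Gaussian naive Bayes (`e1071`);
* `dt` — unpruned CART (`rpart` with `minsplit = 2`, `cp = 0`, matching
  the fully-grown default of scikit-learn-style trees; `rpart`'s own
  conservative defaults cannot split small training sets at all);
* `gbdt` — gradient-boosted trees (`xgboost`, 100 rounds, learning rate
  0.1, depth 3).

The standard split trains on 50 subjects per class and tests on the
remaining 78; smaller cohorts use two thirds of each class. Per-class
accuracy is reported as the true positive rate; per-class FPR and F1 and
the overall accuracy complete the metric set. Serialized runs repeat the
split/fit over derived seeds (default 30 at full scale) and aggregate each
metric as mean, sample SD and max, optionally discarding runs under a
performance floor (default 0: keep all).

ROC summaries fit the one-parameter concave family
$\mathrm{TPR} = \mathrm{FPR}^{1/\theta}$, $\theta \ge 1$, to the per-run
(FPR, TPR) points by least squares — monotone, endpoint-constrained, and
robust with few points — and integrate the fitted curve with composite
Simpson's rule on 101 uniform points (exact through cubic polynomials).

The ensemble rule combines one prediction per model: for each class,
multiply $(1 - \text{accuracy on that class})$ over the models that
predicted it (probability that all of them are wrong); a class predicted by
no model scores 1; the smallest score wins, ties breaking in the fixed
order healthy, gof, lof.

# Problem sizes, reproducibility, and what the tests show

The full-scale experiment — 228 subjects, 200 neurons, 1 s, 30
serializations — is provided as `scripts/full_experiment.R` and takes hours
on one CPU, most of it in the quadratic sample-entropy and
false-nearest-neighbor estimators. The package's tests and
`scripts/acceptance.R` therefore run a reduced design chosen once: 10
subjects per class, 50 neurons on a 10 × 5 lattice (33 excitatory, 17
inhibitory — the full-scale E:I ratio), 500 ms of activity. At this scale
the class physiology (gain-of-function hyperactivity, healthy/lof
proximity), the feature screen (about two thirds of the 92 features
retained at α = 0.02, comparable to the full design), and above-chance
multiclass classification are all reproduced in minutes.

Every stochastic stage consumes a sub-seed derived deterministically from
one master seed (geometry, wiring, initial state, per-subject seeds,
per-run split and initialization seeds), so cohorts, feature tables and
metrics are bitwise reproducible end to end; this is asserted by tests.

What passing reduced-scale tests do **not** show: the simulated signals are
noise-free and far more homogeneous than in vitro microelectrode
recordings; absolute accuracies at reduced scale are noisier than the
full-scale ones (test sets of 12 versus 78 subjects), and conclusions about
real recordings would need validation on data with biological and
measurement noise. The healthy/lof contrast in particular rests on subtle
subthreshold differences of inhibitory neurons and is the fragile part of
the classification problem — consistent with loss-of-function being the
hardest class in the full design.

# Degenerate inputs and numerical choices

Rate functions with removable singularities are evaluated by series near
the singular point. Zero-variance traces: embedding dimension 1, sample
entropy 0, line length 0, no events, transfer entropy 0 (single-bin
symbolization). Neurons without qualifying PDS/IIS events report zero
durations. Features are validated to be finite; a non-finite feature aborts
extraction naming the feature. Subject failures in a cohort are skipped
with a warning; more than 5% failures aborts the run.
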