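---
title: "Methods: nonlinear MVAR directed connectivity and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonlinear MVAR directed connectivity and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ncreann` estimates directed interactions between M simultaneously recorded
neural signals under a nonlinear multivariate autoregressive (nMVAR) model:
the current sample of every node is an unknown function of the p previous
samples of all nodes plus an innovation,

    x(n) = f(x_p) + e(n),   x_p = (x_1(n-1), ..., x_M(n-p)).

A single-hidden-layer perceptron (tanh hidden units, linear outputs,
H = 10 by default) implements f. A first-order Taylor expansion of the
trained network at the expansion point x = 0 splits the map into a linear
part — lag matrices `A_d` with entry `A_d[j, i]` the linear weight of
`x_i(n-d)` in `x_j(n)` — and a nonlinear remainder. Two directed summaries
follow:

* **Linear connectivity** `lC[j, i]` (edge i to j): the mean over lags of
  `|A_d[j, i]|`.
* **Nonlinear connectivity** `NC[j, i]`: the log ratio of node j's
  prediction error when node i is restricted to act only linearly
  (its lag columns replaced by the expansion point in the network input,
  with the linear contribution added back: `f(x_tilde) + A (x - x_tilde)`)
  over the error of the full network. Positive values mean node i
  contributes nonlinearly to node j.

Because inputs and targets are standardized per node and lag before
training, the expansion point 0 is the data mean, the Taylor split is
well-conditioned there, and all connectivity values are amplitude-free
(doubling every signal changes nothing, which the test suite checks
bit-for-bit). The intercept term of the expansion (`W2 g(b1) + b2`) enters
neither summary: connectivity must not depend on offsets.

Self-connections (the diagonal of `lC` and `NC`) are estimated and
reported but excluded from all network-level averages.

## Training

Rows `(x(n); x_p)` are pooled over trials, never across a trial boundary.
Each of `folds` repetitions draws a fresh random permutation splitting the
rows 80% / 10% / 10% into training, validation and test sets. Weights start
uniform in [-0.5, 0.5] and are updated in incremental (per-pattern) mode by
gradient descent with momentum (0.9) and an adaptive learning rate
(initial 0.01). The rate schedule is: grow by 1.05 after an epoch that
lowers the training error; reject the epoch's update and shrink by 0.7 when
the error grows by more than 4%; shrink by 0.7 (keeping the update) when
the error neither improves nor degrades beyond that band. The last rule
anneals the per-pattern updates once they reach their noise floor — without
it, incremental updates orbit the optimum at a distance set by the learning
rate and the linear coefficients never reach least-squares accuracy. Early
stopping keeps the best-validation weights and halts after `patience = 6`
stale epochs (cap 200). A non-finite epoch error triggers up to five
rate-halvings before aborting.

`lC` is averaged over folds. `NC` is computed on each fold's held-out test
rows and then averaged — test-set errors keep the log-ratio free of the
optimism a training-set evaluation would leak into it. Fit quality is
reported as MSE and pooled R² on training and test partitions of every
fold. All stochastic pieces (initialization, splits, pattern order,
surrogates) derive from one integer seed through counter-based substreams,
so every result is bit-reproducible.

The model order is chosen by fitting ordinary least-squares linear VARs for
p = 1..p_max on a common effective sample and minimizing
`AIC = ln det(S) + 2 p M^2 / n` and `BIC = ln det(S) + p M^2 ln(n) / n`;
the consensus is the smaller of the two argmins.

## Significance: time-shifted surrogates

Each of the (default 100) surrogate datasets applies an independent
circular shift, uniform in [0.1 T, 0.9 T], to every node within every
trial. Shifts preserve each series' spectrum and internal dynamics but
destroy cross-signal timing, hence any directed relation. The full
fit-and-extract pipeline runs per surrogate with the real configuration;
the per-edge threshold is the 95th percentile of the surrogate values and
an edge is significant when the real estimate exceeds it. On independent
noise this construction is exchangeable by design, so the expected
significance rate is 5/101 per edge — the calibration the acceptance suite
verifies.

## Sensor and source stages

**Time-frequency.** Complex Morlet wavelets (Gaussian envelope SD
`n_cycles / (2 pi f)`, five cycles by default, unit-energy normalization)
are convolved per trial; squared magnitudes are averaged over trials with
no evoked subtraction. Samples where the wavelet support overruns the
epoch are marked invalid per frequency, and band power refuses windows
touching them. The default grid is 2-30 Hz in 1 Hz steps, covering theta
(4-7), alpha (8-12) and beta (12-25 Hz). A periodogram-based
`band_power_psd()` provides the same per-channel summary without time
resolution for large simulation studies.

**Band-pass.** Hamming-windowed sinc FIR filters; the order follows the
Hamming design rule from a transition width of `max(2, 0.25 f_lo)` Hz
(~53 dB stop-band). Application is zero-phase (forward-backward) by
default. Zero-phase filtering is non-causal and can in principle smear
directed-causality estimates backward in time; a causal single-pass mode
with group-delay compensation is exposed for sensitivity analyses, and the
choice is deliberately a visible parameter rather than a buried default.

**Cluster statistics.** Paired t per channel, two-tailed threshold at
`alpha_cluster`, spatial clustering of supra-threshold channels by an
adjacency matrix (neighbors = inter-sensor distance below a configured
cutoff; a minimum cluster of two channels), cluster mass = within-cluster
t-sum, and a Monte-Carlo null (default 500 draws) of the maximum absolute
cluster mass under within-subject condition sign flips, with the +1-smoothed
p estimator. On a four-subject toy the Monte-Carlo p equals exhaustive
enumeration over all 16 sign patterns exactly. Empirically the family-wise
error rate sits near 0.03 — cluster tests of this construction are mildly
conservative, which the validation suite's tolerance band reflects.

**Beamforming.** LCMV with a common spatial filter: the covariance comes
from the concatenated per-condition time-locked averages, so both
conditions are projected through identical weights and condition
differences cannot be filter artifacts. Regularization is Tikhonov loading
at 5% of the mean eigenvalue. Orientation is fixed per voxel to the
maximum-power direction (dominant eigenvector of the 3x3 source
covariance, equivalently of `(L' C^-1 L)^-1`), and weights satisfy unit
gain `w' l = 1` to 1e-6. The neural activity index divides beamformer
output power by projected noise power; the default noise covariance is the
identity scaled to the smallest data-covariance eigenvalue, a
unit-noise-gain style normalization chosen because no specific noise
estimate is canonical here. High-NAI voxels (top 1% among atlas-labeled
voxels, ties broken by voxel index) are clustered with DBSCAN (eps = 1.5
voxel edges, minPts = 2); the interactive inspect-and-merge step of manual
workflows is replaced by two deterministic rules (size floor; merge
same-label clusters with nearby centroids) because reproducibility
excludes human-in-the-loop steps. Cluster activity is the arithmetic mean
of member-voxel time courses per trial.

## The synthetic-data module

Every pipeline stage is validated against generators with known truth:

* `simulate_nmvar()`: nMVAR systems with explicit lag matrices and a fixed
  nonlinear term library — squares, tanh saturations, and cross-products
  of two lagged values — spanning polynomial and smooth saturating
  nonlinearities; a Taylor-based estimator should capture the former's
  effects and remain honest about the latter. Residuals are i.i.d.
  Gaussian (the weakest assumption consistent with an unspecified
  innovation term); burn-in is `max(10 p, 100)` samples; non-stationary
  coefficient stacks (companion spectral radius >= 1) are rejected.
* `simulate_band_trials()`: two-condition epochs with 1/f background on
  all channels and narrowband bursts on designated channel groups. The
  per-subject fractional amplitude gap between conditions is drawn so its
  across-subject Cohen's d equals the requested effect size; a gap scale of
  0.3 and log-normal subject jitter (10%) keep amplitudes positive and
  realistic. With zero effect the two conditions are exchangeable, which
  is what makes the type-I calibration exact.
* `simulate_source_projection()`: planted dipoles projected through a
  synthetic leadfield (`synthetic_source_model()`: a 10x10x10 lattice,
  5 mm edges, random smooth topographies, integer block labels standing in
  for an atlas — explicitly synthetic, with no head-model physics).
* `simulate_behavior()`: scores with an exact population correlation to a
  connectivity summary.
* `simulate_connectivity_study()`: the end-to-end fixture. An acyclic
  3-node VAR(2) whose per-node innovation variances are solved (one
  Lyapunov system) so every node has unit stationary variance; then the
  standardized coefficients equal the generating ones and the network-mean
  linear connectivity is exactly linear in the coupling scale, letting the
  condition effect be planted in closed form. Per-subject condition
  differences are `N(d * s0, s0)` with `s0` = 50% of the baseline network
  mean — matching the roughly 50% between-subject coefficient of variation
  typical of such connectivity estimates. Both conditions of a subject
  share innovation noise and fit seeds (common random numbers): a paired
  synthetic design in which estimation error largely cancels from the
  within-subject difference, so the planted effect size survives to the
  group test. Real paired EEG data share no noise across conditions; the
  fixture therefore demonstrates direction recovery at the planted effect
  size, not the additional attenuation real estimation noise would cause.

What the generators do **not** emulate: volume-conduction mixing into the
connectivity stage, artifacts (blinks, muscle), trial-to-trial
nonstationarity, non-Gaussian innovations, and realistic head geometry.
Passing tests therefore certify the estimator and statistics under the
stated model assumptions, not robustness to every property of real EEG.

## Numerical choices and problem sizes

* Standardization is per design column (node x lag) and per target; the
  stored centers/scales make the z-transform exactly invertible.
* The "low-noise" fit-quality fixture uses near-resonant AR(2) nodes
  (pole radius 0.995): R² equals the linearly predictable variance
  fraction, and poles near the unit circle push it above 0.99 — an analog
  of the high R² regime reported for well-trained networks on band-limited
  cortical sources, where narrowband signals are similarly predictable.
* Validation studies run at deliberately modest sizes chosen for tight
  Monte-Carlo error at interactive runtimes: 10-20 seeds per property,
  n = 20,000 samples for coefficient-recovery checks, 200 replicates x
  500 permutations (20 subjects, 32 channels) for the cluster type-I
  study, 100 surrogates per significance test, and 40-subject end-to-end
  studies with 10 trials x 384 samples per condition.
* The end-to-end direction-recovery property sits intentionally at the
  edge of its power curve: a planted d = 0.5 at n = 40 gives one-sided
  paired-t power of roughly 0.92, so a >= 90%-of-seeds check is a sharp
  test of whether the pipeline preserves the planted effect size.

## Known limitations

* The Taylor split is exact only at the expansion point; strongly
  nonlinear regimes far from the data mean can leak into `lC`.
* `NC` compares restricted and full predictions of the *same* trained
  network; it measures the network's reliance on a node's nonlinear
  contribution, not an absolute nonlinearity measure.
* Incremental training is stochastic: node-relabeling equivariance holds
  statistically (to ~0.05 in connectivity units on converged fits), not
  bit-wise.
* Zero-phase band-pass filtering before a causal estimator is the field's
  habit but not causally innocent; both filter modes are exposed.
* The I/O container is a plain-text directory format (full-precision CSV
  plus JSON metadata) — portable and lossless, chosen over binary
  scientific containers to keep the package dependency-light.
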