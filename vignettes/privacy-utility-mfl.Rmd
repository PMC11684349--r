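---
title: "Balancing stress recognition against re-identification: the methods behind fedstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balancing stress recognition against re-identification: the methods behind fedstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Wearable physiological channels — electrodermal activity (EDA), blood volume
pulse (BVP), tri-axial acceleration (ACC), skin temperature (TEMP),
optionally ECG — carry two kinds of information at once: the wearer's
*state* (stressed vs. not) and the wearer's *identity* (baseline levels and
spectral signatures are biometric). A model trained to recognise stress in a
federated setting therefore leaks identity through its shared parameters.
`fedstress` implements and studies one mitigation: train a multitask network
with a shared trunk, a stress head and an identity branch, federate it with
FedAvg, and inject differential-privacy (DP) noise *selectively* into the
identity-specific layers of each client's upload, so that re-identification
degrades while stress recognition survives.

Because the real datasets this design was developed on are external
downloads, the package ships a seeded synthetic generator whose identity
separability and stress effect size are controllable; every claim the test
suite makes is about this synthetic system, not about real wearable data
(see "What the generator does and does not emulate").

## Pipeline and model

Signals are segmented per modality at native rate into 700-sample windows
with 50% overlap; each window is summarised by 12 features (mean, unbiased
variance, RMS, moment skewness, excess kurtosis, Shannon entropy of a
16-bin equal-width amplitude histogram, mean absolute first and second
successive differences, and four log-spaced raw-periodogram band powers
between Nyquist/100 and Nyquist). Feature blocks are concatenated across
modalities by window ordinal; the stress label is the majority state in the
window (ties to stress), the identity label is the subject id.

The classifier is a 1D CNN over the feature vector: three stride-1,
kernel-8, zero-padded convolutions (20/40/60 channels), each followed by
ReLU and stride-2 max pooling; a 100-unit shared fully connected layer
(fc1); a linear 2-class stress head off fc1; and an identity branch
(fc2: 100 to 300, ReLU, then a linear N-class head). Padding is asymmetric
(3 left, 4 right) so convolutions preserve length and only pooling halves
it; a 48-wide input therefore flattens to 60 x 6 = 360 units. The loss is
the unweighted sum of the two softmax cross-entropies — never reweighted.
Scopes partition the parameters: conv1-3 and fc1 are `shared`, the stress
head `stress_specific`, fc2 and the identity head `identity_specific`; fc2
belongs to the identity branch because only the identity head consumes it.

Local optimisation is minibatch SGD (default batch 32, learning rate
5e-4) on the proximal objective `F(w) + (mu/2) ||w - w_global||^2`;
`mu_prox = 0` (plain FedAvg) is the default, the proximal knob is exposed
because the local objective admits both readings. Early stopping uses
patience 5 on pooled validation total loss and returns the best-validation
model; set `patience = Inf` to reproduce a fixed number of rounds exactly.

## Federation

`run_training()` partitions the windows into `K` equal shards (`iid`
uniform draws, or `dirichlet` identity-label skew with concentration
`alpha`, rebalanced to equal sizes), holds out 20% of each shard for
validation, and runs `T` rounds of: broadcast, one local epoch per client,
optional DP perturbation of the upload, and FedAvg aggregation — the exact
dataset-size-weighted mean `sum p_i w_i`, `p_i = D_i / D`. All randomness
(partition, splits, batch order, noise) derives from one seed through a
hash-based substream scheme, so runs are bit-reproducible; a `K = 1`
federated run is bit-identical to the centralized trainer, which the test
suite asserts. Features are z-scored with training-pool statistics; the
scaler travels with the returned model.

## Differential privacy mechanisms

Per client and round, the layers in the configured scope (`full`,
`shared`, `identity_specific`, `stress_specific`) are jointly L2-clipped to
`C` and perturbed with i.i.d. noise per coordinate:

* `gaussian_fixed` — fixed sd `sigma` (the sweep mechanism; levels 0.1,
  0.3, 0.6 are studied),
* `laplace` — scale `b = delta_f / epsilon`,
* `gaussian1` — `sigma = delta_f sqrt(2 log(1.25/delta)) / epsilon`
  (the analytic Gaussian mechanism; the `delta_f` factor is part of the
  standard formula and is included),
* `gaussian2` — `sigma = delta_f sqrt(2 q T log(1/delta)) / epsilon`,
  which grows with the round count `T` and sampling fraction `q = K/N`.

Sensitivity defaults to `delta_f = 2C/U_i` (per-client-size reading, with
`U_i` the client's training-set size); the worst-case reading `2C` is
selectable because the source formula is ambiguous between the two. No
moments/Rényi accountant is implemented: reported (epsilon, delta) are
per-round, per-mechanism nominal values.

### What is clipped and noised: weights, not deltas

A design question with large consequences: is the clipped-and-noised upload
the client's *update* (delta to the broadcast model) or its *trained
weights*? The two aggregate identically except for what the norm bound
constrains, and the package supports both (`noise_target`). The default is
`weights`, the client-level scheme of the personalised-FL lineage this
design follows, and our experiments show the choice is not cosmetic. With
update-space noise the scoped branch performs a random walk — per-round
noise is never removed, so branch weights grow without bound. Two
pathologies follow: the huge branch amplifies the effective gradient scale,
so one local epoch re-fits the identity branch on top of each round's noise
(re-identification accuracy recovers almost fully at sigma = 0.6); and the
garbage gradients backpropagated through the exploding branch corrupt the
shared trunk, degrading stress accuracy — jointly the *inverse* of the
intended trade-off. Weight-space clipping caps the uploaded branch at norm
`C` every round, so noise cannot accumulate: the identity branch stays
noise-dominated (re-identification falls to chance) while the unperturbed
trunk keeps learning stress. A residual cost remains at large noise: during
local training the identity loss still backpropagates through the noisy
branch into the shared fc1, and at sigma = 0.6 this measurably drags
stress accuracy down (on the order of 15-25 points on the synthetic
cohort), consistent with the observation that large fixed noise degrades
utility as well. At sigma = 0.1-0.3 the trade-off is clean: stress intact,
identity at chance.

A second dynamical observation worth recording: even under branch noise,
identity information can migrate into the *shared* fc1 layer, which
receives identity-loss gradients but is never perturbed under the
`identity_specific` scope. This is the structural escape route by which a
multitask trunk can defeat branch-only perturbation; weight-space clipping
limits, but does not abolish, it.

## The synthetic generator

Per subject and modality the generator draws, in a documented order from
one seed: a baseline level (population mean plus `identity_strength` times
a modality spread), a signature oscillation gain (`identity_strength`
scaled, non-negative), a signature spectral peak (uniform in a
modality-specific band), and a stress coefficient (`stress_effect` scaled
with a ±20% subject factor). A channel is baseline + signature sine +
state effect + AR(1) Gaussian noise (default coefficient 0.6). Stress
modulates one property per modality: level shifts for EDA (+) and TEMP
(−), a dominant-frequency shift for BVP/ECG (phase-continuous), and a
variance shift for ACC — one effect type per modality keeps per-modality
ablations interpretable. States are binary (stress vs. non-stress) because
the classifiers in scope are binary. Default rates mirror the wrist/chest
device family (EDA/TEMP 4 Hz, ACC 32 Hz, BVP 64 Hz, ECG 700 Hz); a
uniform-rate mode (all channels at 4 Hz) is used throughout the experiment
suite so the 700-sample windows of different modalities are time-aligned
without a resampling toolchain.

Separability presets: `high` (identity_strength 1.0, stress_effect 2.0)
was calibrated once so that the *no-DP* federated operating point
(10 subjects, K = 5, T = 20, D_i = 1000) lands near the published
federated accuracies this study emulates (roughly 0.95 stress, 0.93
identity); `medium` (0.5 / 1.0) sits away from ceiling and chance; `null`
(0 / 0) has no signal and both tasks sit at chance, which the suite checks
with the actual downstream model. The experiment schedule alternates 700-s
state blocks — four window spans per block at 4 Hz — emulating the long
condition blocks of laboratory stress protocols while keeping
boundary-window label noise small.

What the generator does *not* emulate: realistic ECG/PPG morphology,
motion artefacts, sensor drift, missing data, subject-specific *stress
response patterns* beyond a ±20% amplitude factor, and any
identity-bearing structure subtler than baselines and narrow-band
signatures. Consequences: identity is recoverable from first-order window
statistics (easier than in real data), and identity-label skew across
clients does not slow stress convergence, because stress responses are
nearly homogeneous across synthetic subjects — on real data, where stress
signatures are strongly individual, non-IID splits plausibly hurt more.
Passing the synthetic suite therefore validates the machinery and the
direction of the mechanisms, not absolute real-data performance.

## Numerical and design choices

* Window count: `floor((len - window)/stride) + 1`, stride
  `round(window (1 - overlap))`, trailing remainder dropped.
* Zero-variance windows: skewness/kurtosis defined as 0; constant windows:
  entropy 0. Variance is the unbiased estimator; kurtosis is excess.
* Max-pool ties take the first element; odd trailing positions are dropped
  by pooling and receive zero gradient.
* He-normal initialisation, biases zero, deterministic per seed.
* Clipping uses the joint L2 norm over the scoped layers only (scope-local
  sensitivity matches what is perturbed); `min(1, C/norm)` rescaling.
* The Laplace sampler is the difference of two exponentials; its scale and
  both Gaussian calibrations are checked against independent arithmetic and
  by Kolmogorov-Smirnov and variance tests.
* Stratified 5-fold splits are round-robin within (identity, stress)
  strata, so every identity appears in every training fold; window-level
  (not subject-level) folding is deliberate — identity classification of
  never-seen subjects is ill-posed.
* Macro-F1 counts a truth-present class with no correct predictions as 0;
  multiclass AUC is macro one-vs-rest; single-class truth yields NA, never
  0. Binary F1 for the stress task is computed within the macro average
  over both classes.
* Problem sizes in the experiment suite (10 subjects, 631 windows per
  subject, D_i of 100-1000, T of 10-20, 5-10 seeds per comparison) are the
  package's chosen desk-scale study conditions; D_i = 1000 and one local
  epoch per round mirror the published federation settings.

## Known limitations

* No secure aggregation, no privacy accountant across rounds, no
  membership-inference or gradient-inversion attack implementations.
* The empirical DP check is a likelihood-ratio histogram bound on a scalar
  count query — a surrogate demonstrating the mechanism's calibration, not
  a proof about the full training pipeline.
* Fixed-sigma noise levels and (epsilon, delta)-calibrated mechanisms are
  deliberately separate; the source material does not reconcile them, and
  neither do we.
* At sigma = 0.6 the stress task pays a measurable price (see above); the
  clean privacy-utility trade-off lives at moderate noise.
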