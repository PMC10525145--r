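---
title: "Multifaceted ERP characterization and feature fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifaceted ERP characterization and feature fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(erpfuse)
```

# The problem

A stimulus-locked brain response in EEG is not one thing. The same event can
produce (R1) a transient voltage deflection added to the ongoing activity,
(R2) suppression or (R3) enhancement of an ongoing oscillation, and a
stimulus-triggered realignment of oscillatory phase with no amplitude change
at all. The classical average event-related potential (ERP) sees only R1:
averaging over trials cancels everything that is not phase-locked to the
event. Time-frequency (TF) amplitude sees R2/R3 but is blind to pure phase
realignment. A cross-trial phase-synchronization measure sees phase
alignment but not amplitude change. The three views are therefore
*non-redundant*: each carries condition information the others cannot.

`erpfuse` implements this three-view characterization for oddball-style
epoched EEG (rare vs frequent stimuli), and quantifies the non-redundancy
operationally: linear softmax classifiers are trained on each feature alone
and on fused combinations, and the held-out accuracy gain of the fused
models over their constituents measures the complementary information.

# Features

All features are computed from epochs in a `[-1000, 2000]` ms window around
stimulus onset and baselined to the `[-200, 0]` ms pre-stimulus window
(subtraction of the per-channel, or per-channel-and-frequency, baseline
mean).

**ERP.** The arithmetic mean of the selected epochs, baselined per channel.

**TF amplitude.** The continuous wavelet transform
`W(a, b) = a^(-1/2) \int S(t) \psi^*((t - b)/a) dt` is evaluated per trial
with a complex Morlet mother wavelet
`\psi(t) = (\pi f_b)^(-1/2) exp(-t^2/f_b) exp(i 2\pi t)` and scale
`a = 1/f`, so `1/a` is proportional to the analysis frequency. "TF power"
is deliberately the coefficient *modulus* (amplitude), not its square.

**Wavelet phase.** The coefficient angle in `(-pi, pi]` (single-trial
feature; angles are not additive offsets, so it is never
baseline-subtracted).

**Phase synchronization.** At each (channel, frequency, time) point the
phases of the n selected trials are binned into 10 equal bins over
`(-pi, pi]`; with bin probabilities `p_i = count_i / n` and mean `mu = 0.1`
the statistic is `sqrt(sum_i (p_i - mu)^2 / 10)`. It is 0 exactly when the
histogram is uniform and 0.3 exactly when all phases share one bin, and for
i.i.d. uniform phases `E[stat^2] = 0.09/n` (0.00375 at n = 24) — both facts
are verified against brute-force oracles in the test suite.

## Numerical choices

* **Morlet parameterization.** The time-decay parameter (default 0.5) is
  read as the *bandwidth* parameter `f_b` in seconds^2 of a unit-centre-
  frequency mother wavelet; this is the convention in which a single
  "time-decay" number is the named free parameter. The envelope SD is then
  `sqrt(f_b/2)/f` = half a period at `f_b = 0.5`. The convention is isolated
  behind `wavelet_spec()`, so a different reading only changes one
  constructor.
* **Amplitude calibration.** Absolute wavelet units are arbitrary (only
  baselined values reach the classifiers), so coefficients are scaled by
  `2/sqrt(a)` to make a unit-amplitude sinusoid map to modulus 1 at its own
  frequency. The closed-form Gaussian-integral response of the Morlet to a
  sinusoid shows the residual error of this calibration is below 1e-8 for
  all frequencies of interest; the discretized transform stays within 2%.
* **Kernel truncation and edges.** Kernels are truncated where the Gaussian
  envelope falls below 1e-5 of its peak (half-length `2.4/f` s). Epoch edges
  are zero-padded; `edge_margin` records, per frequency, how many samples at
  each end touch the padding. The classifier crop (`[-500, 1500]` ms by
  default) keeps analysis away from the edges for frequencies above ~5 Hz;
  at the lowest frequencies of the default grid some cropped samples are
  still edge-influenced — identically so in both conditions, so condition
  contrasts are unaffected.
* **Bin convention.** Bin i covers `(-pi + (i-1) 2pi/10, -pi + i 2pi/10]`;
  a phase of exactly `-pi` is assigned to bin 1. The statistic is invariant
  to rotating all phases by whole bins.
* **Epoch time axis.** Sample k of an epoch is `t_start + k * 1000/srate`
  ms, with both window endpoints included (451 samples for `[-1000, 2000]`
  ms at 150 Hz). Inclusivity is a convention choice; it is asserted
  centrally in `n_epoch_samples()`.

# Classifiers

Each feature kind is flattened to a vector and mapped by one linear layer to
two logits (frequent = 0, rare = 1). The logits are batch-normalized
(per-logit, learned scale/shift) so that differently scaled features become
commensurate. A single-feature model applies softmax directly; a composite
model concatenates the normalized logit pairs of its k features and applies
one fusion linear map before softmax.

Training is plain SGD (learning rate 1e-4, momentum 0.9) on the mean
cross-entropy, batch size 50 for trial-average samples (1920 and 50 epochs
for single-trial mode), 200 epochs otherwise, with the data order
reshuffled every epoch. The analytic backward pass — softmax, fusion map,
and the full batch-statistics batch-norm backward — is checked against
central finite differences to a relative error below 1e-4.

Composites are *transfer-initialized*: each per-feature block (weights,
bias, normalization state) is copied bit-exactly from the separately
trained single-feature model, and only the fusion map starts fresh. The
fusion map's initialization is not prescribed anywhere, so the package
starts it at *block averaging* (each output logit = the mean of the
corresponding per-feature logits, bias 0): the untrained composite then
reproduces the ensemble of its parts exactly, which is the natural
"start close to the solution" reading of transfer initialization. A
small-random initialization is available via `fusion_init = "random"`.

Other unstated constants fixed in the implementation: batch-norm epsilon
1e-5, running-statistics momentum 0.1 (biased batch variance), evaluation
always uses running statistics, weight initialization uniform in
`+/- 1/sqrt(d)`, prediction ties broken toward the frequent class.

# The sampling protocol

Trial-average mode equalizes trial counts between conditions: per
participant, the one rare sample averages all 24 rare trials, and the 135
frequent trials are partitioned once per cohort into 5 non-overlapping
24-trial subsets; each iteration of the procedure draws one frequent
candidate per participant, giving a class-balanced dataset (400 samples at
200 participants), and re-splits it 25% test / 75% train. Phase information
enters trial-average models as the phase-synchronization statistic.
Single-trial mode uses every rare trial plus an equal number of freshly
drawn frequent trials (4800 + 4800 samples at 200 participants), with the
baselined epoch, per-trial TF amplitude, and raw wavelet phase as features.

Each iteration trains the three single-feature models, transfer-initializes
and trains the four composites, and records held-out accuracy after every
epoch. Trajectories are aggregated across iterations as mean and standard
error of the mean (SEM); the per-iteration summary accuracy is the final
epoch for trial-average runs and the mean of the last 20 epochs for
single-trial runs.

The split is sample-level by default, so one participant's rare and
frequent samples may land on opposite sides — faithful to the reference
protocol. `grouped = TRUE` switches to participant-level splits. This
matters at small cohort sizes: with tens of samples, a linear model can
memorize participant-specific background patterns, and a test sample whose
within-participant twin was in training is then systematically
*mis*classified, biasing sample-level held-out accuracy below chance. The
package's scaled validation suites therefore use grouped splits, which make
the measured accuracy a statement about generalization across participants;
at full scale (hundreds of samples, batch 50) the memorization pressure is
far weaker and the default sample-level split is appropriate.

# The synthetic cohort generator

No real recordings ship with the package; the generator produces oddball
cohorts whose condition effects can be placed *selectively* into the ERP,
TF-amplitude, or phase channel:

* **Background**: Gaussian noise spectrally shaped to `1/f^alpha`
  (default `alpha = 1`, RMS 8 microvolts, high-pass floor at 0.5 Hz),
  independent per trial and channel — broadband EEG background without any
  claim of physiological detail.
* **Transient sources** (R1): Gaussian bumps (peak latency 350 ms, FWHM
  300 ms by default) with per-trial Normal latency jitter and LogNormal
  amplitude variability (mean 1, configurable CV).
* **Ongoing oscillations** (R2/R3): single-frequency sinusoids with
  uniform per-trial phase. Post-stimulus suppression/enhancement is a
  raised-cosine gain ramp (200 ms) to the target gain — smooth to avoid
  spectral splatter. Phase resets ramp the phase offset from its free
  pre-stimulus value to the target over 400 ms with the envelope untouched;
  the slower ramp caps the instantaneous-frequency excursion at about
  1.25 Hz so that a reset remains, as it should be, a phase effect that is
  nearly invisible to TF amplitude. A *bimodal* reset (fair coin between
  `phi` and `phi + pi`) additionally cancels in the trial average, making
  it invisible to the ERP by symmetry.

The `make_scenario()` presets plant exactly one effect each: `erp_only`
(transient amplitude 6 vs 2 microvolts; its spectral content lies below the
4-14 Hz analysis band, so TF features stay clean), `tfpower_only` (a
free-phase 10 Hz rhythm of 6 microvolts suppressed to gain 0.4 after rare
stimuli), `phase_only` (a 6 Hz rhythm bimodally reset after rare stimuli),
plus `combined` and `null`. The 6 Hz source amplitude (12 microvolts at the
topography peak) is chosen so that single-trial phase at that frequency is
estimable against the background (wavelet-band background modulus is about
3.4 microvolts at 6 Hz): a pure phase effect that cannot be estimated on
single trials would be invisible to *every* feature and probe nothing.
Full reproducibility holds by construction: every participant, source and
stage draws from its own seed substream, which also makes the simulated
data exactly linear in its sources.

What the generator does *not* emulate: volume conduction from a head model,
spatially correlated noise across channels, ocular/muscle artifacts,
non-sinusoidal rhythms, inter-participant variability of source parameters.
Passing tests on this generator therefore demonstrate that the pipeline
measures what each feature is defined to measure and that fusion recovers
complementary information — not that any particular accuracy level will be
reached on real recordings.

# Study sizes used in validation

The validation suites run a scaled cohort: 12 participants, 8 channels,
6 analysis frequencies (4-14 Hz), the full 24 rare / 135 frequent trial
structure, 5-8 procedure iterations, grouped splits. Protocol *counts*
(400 samples, 5 frequent subsets, 100/300 split, 4800 + 4800 single-trial
samples) are verified at the full 200-participant geometry, where they are
exact consequences of the sampling scheme. Full-scale feature/classifier
settings remain available (`scale: paper` in the CLI configuration).

# Known limitations

* The classifiers are linear by design; they quantify first-order
  (magnitude) condition information in each feature and say nothing about
  nonlinear or cross-feature structure.
* The phase-synchronization statistic depends on the 10-bin histogram; it
  is coarser than resultant-vector phase locking for small n and smeared
  multimodal distributions, and its sampling null mean (`sqrt(0.09/n)` in
  expectation of the square) must be compared across equal trial counts —
  which the equal-count sampling protocol guarantees.
* EDF import is minimal (16-bit EDF, one sampling rate across channels);
  preprocessing (filtering, artifact removal, ICA) is out of scope — the
  package consumes cleaned continuous or epoched data.
* With `n_frequent = 135` and 24-trial averages, 15 frequent trials per
  participant are never used in trial-average mode; this mirrors the
  non-overlapping-subset design rather than maximizing data use.
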