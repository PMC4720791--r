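---
title: "Methods: simulating and detecting motor intention in EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting motor intention in EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

A brain switch for motor rehabilitation must detect, from ongoing scalp
EEG, that the user has just imagined a movement — and do so within a few
hundred milliseconds, because associative plasticity protocols require the
afferent feedback triggered by the switch to arrive near-synchronously with
the intent. Two EEG signatures carry the relevant information over the foot
area of sensorimotor cortex (electrode Cz): the movement-related cortical
potential (MRCP), a slow 0.05–3 Hz negativity peaking near movement onset,
and sensorimotor rhythms (SMR), band-limited oscillations whose power drops
(ERD) around imagery and rebounds above baseline (ERS) afterwards. The
package implements both the morphology statistics that characterise these
signatures and a pseudo-online detection pipeline that exploits them, and —
because no public recordings accompany the design it follows — a seeded
session generator with known ground truth against which everything is
validated.

## The session generator

A session consists of `n_runs` runs of `trials_per_run` trials; each trial
is an idle (5 s), focus (2 s), preparation (3 s) and task (4 s) phase, with
one cue event at each task onset (so consecutive cues are 14 s apart) and a
trailing idle phase closing the session so the last trial has full
post-cue context. Nine channels (Cz plus Fz, F3, F4, C3, C4, P3, P4, Pz)
are synthesised at a configurable rate, default 1200 Hz.

**MRCP template.** Piecewise raised-cosine segments parameterised by the
morphology landmarks reported for imagined dorsiflexion: a smooth fall from
0 at t = −2 s to the peak negativity −A at the cue. The ballistic template
rebounds through a small overshoot (+0.15 A at 1 s) back to baseline by
2 s; the small overshoot matters because the ballistic deflection should be
statistically indistinguishable from baseline shortly after 1 s while still
"returning to baseline in about 2 s". The repetitive template relaxes onto
a −0.6 A plateau sustained through the 4-s task phase and decays to zero by
6 s, producing the prolonged post-onset significance characteristic of
repetitive imagery. Raised cosines keep the waveform C¹ and band-limited.

**SMR carriers.** Each configured band is an amplitude-modulated
band-pass-filtered white-noise carrier (4th-order Butterworth), not a pure
sinusoid — real rhythms are nonstationary. The power-gain envelope is 1 at
baseline, dips to 1 − ERD-depth during the ERD window and rises to the ERS
gain in the ERS window (raised-cosine bumps); the carrier is multiplied by
the square root of the envelope so that the *power* follows it. For the
repetitive task the ERD is stretched to cover the whole task phase and the
ERS onset is delayed by 2 s, implementing the delayed beta rebound of
sustained imagery; the delay guarantees the repetitive ERS peaks strictly
later than the ballistic one for any band specification.

**Noise.** Per channel, pink (1/f-spectrum, flattened below 0.1 Hz so the
variance is finite) plus white noise; a `mixing` fraction of each
component's power is a source common to all channels, emulating
volume-conducted background. The log-log PSD slope of the pink component
over 1–40 Hz is −1 by construction and is verified by a Welch fit in the
tests.

**Free parameters and their defaults.** The study design this package
follows quantifies neither the MRCP amplitude in µV nor the SMR modulation
depths, so these are free parameters with defaults chosen once to be
realistic for imagined dorsiflexion in healthy adults: peak MRCP
negativity 10 µV; background pink 8 µV RMS and white 2 µV RMS per channel
with mixing 0.6 (after the Laplacian this leaves roughly 4 µV of in-band
background against a 7 µV effective MRCP peak — a moderate, realistic
single-trial SNR); an alpha rhythm (10.5 ± 2.5 Hz, 4 µV, ERD depth 0.5)
and a beta rhythm (21 ± 4 Hz, 3 µV, ERD depth 0.3, ERS gain 1.8). Source
amplitudes are expressed at the virtual-Cz level: the injection is scaled
by the inverse of the spatial profile's Laplacian gain (default profile:
1.0 at Cz, 0.3 at the neighbours), so that with zero noise the epoch
average recovers the template exactly — the ground-truth-recoverability
invariant the tests assert at 1e−9 relative tolerance.

**Determinism.** One RNG seed per session; `generate_session()` is a pure
function of its configuration, which the tests check bit-for-bit.

## Preprocessing conventions

- **Filtering** is a 2nd-order Butterworth band-pass per channel. The
  detection path uses a single causal forward pass (every sample of the
  stream must be computable from the past); the morphology path uses
  forward–backward filtering, standard for averaging because it has zero
  group delay. Both are exposed via the `mode` flag.
- The **virtual Cz** is exactly `Cz − mean(eight neighbours)`; filtering
  and the Laplacian are both linear, so their order is immaterial — the
  pipeline filters first, as conventionally stated.
- **Epochs** span [−3, 6) s around each cue (half-open, so a 9-s epoch at
  rate fs holds exactly 9·fs samples); no implicit baseline subtraction.
  The reference interval [−3, −2) s is carried as metadata.
- **Sliding windows** are 2 s long, advanced 0.1 s, and indexed by their
  *trailing edge* — the causal convention, since a detection timestamp may
  only refer to already-observed samples. A window is labelled *signal*
  when its trailing edge lies in the half-open interval (cue − 1, cue + 1]
  for some cue. The boundary convention is a package decision (the
  underlying description does not state inclusivity); window/label tests
  run on integer sample indices to avoid floating-point boundary jitter.
  With isolated cues this yields exactly 20 signal windows per cue.

## Morphology statistics

**MRCP profile.** For each 0.1-s segment outside the reference interval,
the per-trial segment mean is compared to the per-trial reference mean with
a paired t-test; Holm–Bonferroni (step-down, via `stats::p.adjust`)
controls the familywise error over all segments jointly at α = 0.05. The
segment statistic is the segment mean — the natural reading of a
"segment magnitude". The t-tests are computed vectorised from the paired
t statistic; tests verify equality with `stats::t.test(paired = TRUE)` and
a 1000-replicate null simulation keeps the familywise error within two
standard errors of α.

**Time-frequency map.** Per trial, 1-s Hamming-tapered periodograms slide
across the epoch with 0.5-s overlap (1-Hz resolution at integer sampling
rates), density-scaled so power integrates to variance; averaging across
trials gives A(f, t). The reference power R(f) is the trial-averaged power
of the windows wholly inside the reference interval (on the default grid,
exactly one window). Relative power is SMR% = (A − R)/R — positive = ERS,
negative = ERD — which is scale-invariant and undefined when R = 0 (a
degenerate-reference error, rather than silent NaNs).

**Bootstrap mask.** Trials are the exchangeable unit: trial indices are
resampled with replacement, once per replicate and shared across the whole
grid so that A and R are recomputed coherently. The per-point statistic is
the mean over trials of the per-trial difference between the point's power
and the trial's reference power. The interval is a *symmetric studentized*
(bootstrap-t) one — the bootstrap quantile of the absolute studentized
statistic — rather than a percentile interval: single-periodogram powers
are strongly non-Gaussian and the percentile interval measurably
over-flags on null data at the default 60-trial session size, while the
symmetric studentized interval stays at its nominal per-point level (both
facts are established by the null-calibration tests). The mask is
uncorrected per-point at α = 0.05, matching the usual presentation of
ERD/ERS maps where only bootstrap-significant points are displayed;
`n_boot` defaults to 1000 and the resampling is seeded.

## Detection pipeline

**Features.** The time-series branch uses the window's band-filtered
virtual-Cz samples after FIR-anti-aliased decimation (default factor
`sampling_rate/20`, i.e. ~40 samples per 2-s window, the conventional
scale for MRCP template features); no amplitude normalisation. The subband
branch uses Welch powers at the 1-Hz frequencies inside the band (so Beta
16–30 Hz gives 15 features), with no dimensionality reduction — the
feature count is already small.

**LPP.** The Locality Preserving Projection builds a k-NN graph
(default k = 5) with heat-kernel weights (width defaulting to the mean
squared pairwise distance — a self-tuning scale), and solves
X L Xᵀ a = λ X D Xᵀ a for the m (default 10) smallest-eigenvalue
directions. These hyperparameters are not fixed by the underlying design
and are exposed in the API. Numerics: an energy-preserving SVD
pre-projection (99% energy) guards rank deficiency; X D Xᵀ gets a relative
ridge of 1e−8 before Cholesky factorisation; the symmetric reduced problem
is solved by a dense symmetric eigensolver. The map is purely linear (no
centring), so projections scale homogeneously. Zero-variance features,
coincident observations, and rank below m raise degenerate-data errors
rather than emitting non-finite scores. The projection subspace is checked
against an independent dense generalized-eigensolver oracle to principal
angles below 1e−6. The k-NN graph is unsupervised; class-aware graph
construction would be a separate extension.

**LDA.** Closed-form pooled-covariance discriminant; priors default to the
empirical training proportions (the signal class is rare, roughly 1:6, and
the detector's operating point is subsequently set by WN calibration, so
the honest priors are used); an equal-prior mode is a flag. Optional
diagonal shrinkage for near-singular feature sets. Verified against a
hand-computed closed form and against `MASS::lda` as an independent
reference.

**Brain switch.** A detection fires at the trailing edge of the WN-th
consecutive signal-classified window; the counter then resets and a 2-s
refractory period ignores subsequent windows — without it a single
sustained activation would flood the false-positive count. The refractory
duration is a package decision. Detector behaviour is verified by
exhaustive enumeration against an independently written oracle over all
label streams up to length 12 for WN 1–4, and the detection count is
non-increasing in WN.

**Scoring.** DL = detection time − nearest cue time; a detection is a true
positive iff DL ∈ (−1, 1] (half-open, consistent with the window labels)
and its cue has no earlier TP — the first detection in the window takes
the credit, later ones count as false positives. TPR = % of cues with a
TP; FP/min divides the false positives by the full evaluated duration,
idle phases included (the switch is armed continuously); DL statistics are
reported in ms over TPs only.

**Calibration and cross-validation.** Runs are the cross-validation unit:
each run is held out once, the other runs train the models. WN is chosen
per fold on the *training* runs only — the smallest WN with training
FP ≤ 8/min (falling back to the largest candidate with a warning if none
qualifies) — so the held-out stream never informs its own operating point.
Fold metrics are pooled by summing counts and durations; the per-fold
breakdown is also reported, since either aggregation is defensible.

## Problem sizes used by the tests

The generator's default rate is 1200 Hz, but every stage accepts any rate,
and the test suite and acceptance script run sessions at 240 Hz with
3 runs × 20 trials: 240 Hz keeps the 2-s/0.1-s window grid and the
~40-sample decimated feature vectors exact while keeping the full
cross-validated pipeline comfortably fast on one CPU. Null-calibration
simulations use 50 Hz epochs (the profile's segment statistic and the 1-Hz
power grid are rate-independent at or above that scale).

## What the generator does and does not emulate

It emulates the trial structure, the two task-specific MRCP morphologies,
band-specific ERD/ERS including the delayed repetitive beta rebound, a
Cz-centred spatial profile, and correlated 1/f + white background. It does
**not** emulate EMG contamination or overt movement (so no EMG-based trial
rejection is implemented), ocular artifacts, inter-subject variability in
SMR topography, electrode impedance drift, or non-stationary noise floors.
Consequently, passing tests demonstrate that the pipeline recovers known
ground truth under realistic stationary noise — not that it would reach the
same numbers on recorded subject data, where artifact handling and
subject-specific band selection matter.

## Known limitations

- Both task templates are deterministic and equally time-locked to the cue,
  and the true-positive window (−1, 1] s rewards the pre-onset negativity
  that the two tasks share. The detection advantage of ballistic over
  repetitive imagery reported on recorded subjects — usually attributed to
  the trial-to-trial variability and less distinct rebound of sustained
  imagery — therefore need not appear on these synthetic sessions, and the
  package does not assert it.
- The repetitive-task detector sees the same signal/noise labelling as the
  ballistic one; no attempt is made to model within-task repetition
  structure in the labels.
- SMR + MRCP feature fusion, nonlinear classifiers and adaptive retraining
  are out of scope.
- The per-point bootstrap mask is uncorrected for multiplicity by default
  (a corrected variant is available through `holm_bonferroni()` on the
  per-point p-values of any other test the user runs); the three-way
  ANOVA/Tukey machinery over the full performance grid is deliberately not
  reimplemented — the grid is exported as a tibble/TSV for any standard
  statistics tool.
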