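---
title: "Methods: simulating and analysing P1/N170 responses to human- vs AI-framed recommendation agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing P1/N170 responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpnat)
```

## The study design this package implements

A recommendation agent is presented in a prime-target trial; the target
carries the agent's identity (human vs. AI) through two visual modalities
at once: a face image and a text label. Participants judge whether a
recommendation from that agent in a symbolic-consumption context feels
natural (key 1) or unnatural (key 2). The electrophysiological readout is
the amplitude of two early visual components of the event-related
potential (ERP):

* **P1**, a positive deflection peaking near 100 ms over
  parietal-occipital sites, searched in **70-130 ms**;
* **N170**, a negative deflection near 170 ms, category-specific for text
  (left site **P7**) and faces (right site **P8**), searched in
  **150-200 ms**.

The analysis is a 2 (identity: human/AI) x 2 (modality: text-P7 /
face-P8) within-subjects design on adaptive-mean amplitudes, restricted to
the two hypothesis-concordant trial types: *human judged natural* and *AI
judged unnatural*. Subjective 7-point ratings (attitude toward the
recommended brand; perceived naturalness of the recommendation) are
compared within subject across agents.

## Pipeline

The preprocessing chain is fixed and order-enforced:

1. **Band-pass filter** 0.3-30 Hz. Realised as a forward-backward
   (zero-phase) 4th-order Butterworth filter, the standard digital
   realisation in ERP practice: at a 1000 Hz rate a linear-phase FIR with a
   0.3 Hz edge would need on the order of 10^4 taps, while the
   forward-backward IIR pass costs a few milliseconds per channel and
   leaves component latencies untouched. The test suite verifies <5%
   leakage at 50 Hz, <5% error at 10 Hz, zero lag, and DC rejection.
2. **Segmentation** into [-200, 1000) ms epochs around each target onset
   after adding the **11 ms display-offset correction** measured for the
   stimulation chain; only human-natural and AI-unnatural events are kept.
   Conventions: 0-based sample indices, half-open windows, ms-to-samples by
   rounding.
3. **Artifact detection** with the moving-average max-minus-min statistic:
   smooth with a centred 80 ms boxcar (81 samples at 1000 Hz, shrinking at
   the edges), then take max minus min. A scalp channel is bad in a
   segment above **200 uV**; a channel bad in more than **20%** of
   segments is bad in all; a segment is rejected with more than **10** bad
   channels, a vertical-ocular range above **140 uV** (blink) or a
   horizontal-ocular range above **55 uV** (eye movement). The acquisition
   software's exact moving-average semantics are not public; the
   plausible alternative — the largest max-minus-min inside any single
   80 ms window — is implemented behind
   `artifact_criteria(method = "windowed_range")`, with smooth-then-range
   as the default. The >200 uV rule is applied to scalp channels only;
   ocular channels are screened by their own thresholds.
4. **Bad-channel replacement** by inverse-distance-weighted means of good
   neighbours (symmetrised 3-nearest-neighbour map on the unit sphere).
   Spherical splines would also be reasonable; for the sites this analysis
   reads (P7/P8) the difference is immaterial, and the weighted mean has
   an exact closed form the tests check. A bad channel with no good
   neighbour rejects its epoch (`uninterpolatable`).
5. **Baseline correction** over [-200, 0) ms.
6. **Average re-reference** across scalp channels (ocular channels stay on
   the recording reference). The scalp channel sum is zero at every sample
   afterwards, which the tests assert to 1e-9.

Per-subject condition averages are plain arithmetic means over retained
epochs; the grand average weights subjects equally regardless of retained
epoch count. Amplitudes are **adaptive means**: locate the polarity
extremum inside the component window (earliest sample wins ties), then
average over peak +/- 10 ms clipped to the window. The 10 ms halfwidth is
conventional for sharp early components and configurable via
`component_window()`.

## Statistics

* **Normality gate**: Shapiro-Wilk per measure family (the rating
  difference scores; each ANOVA effect's within-subject contrast scores).
  Ratings failing the gate go to the Wilcoxon signed-rank test, otherwise
  to the paired t.
* **Wilcoxon signed-rank**: zero differences dropped, mid-ranks for ties,
  tie-corrected normal approximation without continuity correction, plus
  sign-group mean ranks — matching the reporting conventions of the
  commercial statistics package family the field uses. For 12 or fewer
  effective pairs the exact sign-enumeration distribution is used
  automatically. The normal approximation's worst-case deviation from the
  exact two-sided p is a property of the lumpy exact distribution: by full
  enumeration it is 0.127 at n = 5 and falls below 0.05 only from n = 10;
  heavy ties inflate it further. The agreement test therefore runs on
  continuous paired sets of 10-12 pairs, the regime where the 0.05 bound
  provably holds.
* **RM-ANOVA**: the 2 x 2 within-subjects decomposition with subject as
  the random block, each effect tested against its own effect-by-subject
  stratum, df = (1, n-1). Fitted with base `aov()` error strata; the
  independent check in the tests is the algebraic identity F = t^2 of the
  paired t on the effect's contrast scores. Partial eta squared is
  SS_effect / (SS_effect + SS_error), identical to F*df1/(F*df1+df2), with
  the conventional labels (small >= 0.01, medium >= 0.06, large >= 0.14 on
  half-open intervals).
* **Planned post hocs**: the four simple effects of the 2 x 2 (within each
  identity, P7 vs P8; within each site, human vs AI), paired t each,
  against the Bonferroni criterion alpha/4 = 0.0125 — four is the contrast
  count that reproduces the study's printed criterion. Post hocs run when
  the interaction is significant.
* Two-sided p-values throughout.

## The synthetic-data generator

No data were deposited by the study, so the generator is a first-class
module that emulates the recording the analysis expects, with fully known
ground truth:

* **Montage**: `n_channels - 2` scalp channels on the unit sphere
  (canonical 10-20 positions first, then a deterministic spherical
  lattice), always containing Cz (reference), P7 and P8, plus one VEOG and
  one HEOG channel. Default 16 channels for test speed; 128 supported.
  The analysis only reads P7/P8, the ocular channels, and neighbours.
* **Paradigm**: 60 target trials (30 human, 30 AI, randomly interleaved),
  each 7.2 s: three 200 ms primes with 300 ms blanks and 200/200/300 ms
  fixations, a 2000 ms target, a 3000 ms blank; responses drawn per
  identity (defaults: P(natural|human) = 0.85, P(natural|AI) = 0.15 — the
  study does not report response proportions, so these are configuration,
  chosen to leave realistic trial counts in the two analysed cells);
  log-normal reaction times truncated at the 5000 ms deadline.
* **Components**: Gaussian bumps (SD = width/4, default width 50 ms)
  at P7 and P8, latencies 100 and 170 ms after the offset-corrected
  onset, with trial-wise latency jitter (SD 3 ms) shared across sites.
  Cell amplitudes are specified **on the adaptive-mean scale**: the
  generator converts a cell's target adaptive mean to the Gaussian peak
  through the closed-form discrete gain, so with noise and jitter silenced
  the downstream extraction returns the profile values exactly (the tests
  check 1%; the observed agreement is ~1e-10). Population cell means
  follow the study's pattern: P1 carries a pure modality effect (P8 5.76,
  P7 4.41 uV, both identities); N170 carries the identity-by-modality
  interaction (human P7 -0.83, human P8 -2.09, AI P7 -2.27 uV, with the
  unprinted AI-face cell set to -1.90 uV to complete the crossed pattern).
* **Between-subject structure**: a common offset per component
  (SD 2.5 uV) plus cell-specific deviations (SD 1.0 uV), which reproduces
  the study's printed cell standard errors (~0.5-0.6 uV at n = 27); white
  channel noise (SD 8 uV) as the testable default — real EEG is
  1/f-coloured, which the generator does not model.
* **Artifacts**: blinks as 300 ms half-sines on VEOG with a 40% frontal
  copy (Poisson, 6/min, ~200 uV), eye movements as 500 ms steps on HEOG
  (4/min, ~80 uV), bad channels as sustained 2 Hz oscillations; all
  calibrated so the detector's smoothed range approximately equals the
  nominal magnitude, i.e. they exist to trip (or stay under) the
  thresholds.
* **Ratings**: a subject trait shared across agents (SD 0.5), an
  agent-specific deviation (SD 0.5) and per-item noise (SD 0.8) around the
  population means (attitude 3.05/3.83, naturalness 2.91/3.57 for
  human/AI); items are rounded into 1-7 and each instrument's score is the
  exact mean of its three items. Under these conditions the within-subject
  attitude gap gives the Wilcoxon test >80% power at n = 27, which the
  test suite measures by simulation.

`simulate_amplitude_cohort()` draws per-subject cell amplitudes directly
(adding a 0.8 uV measurement residual approximating extraction noise),
which makes Monte-Carlo power and type-I-error studies of the statistical
layer essentially free.

## What the adaptive mean can and cannot recover

Three properties of polarity-constrained extremum measures matter when
interpreting recovery tests; all are estimator properties, not
implementation defects (deterministic recovery is exact):

1. **Latency jitter attenuates averaged peaks.** Averaging trials whose
   latencies jitter with SD j widens the mean bump from SD s to
   sqrt(s^2 + j^2) and scales its peak by s/sqrt(s^2+j^2) (~3% at the
   defaults).
2. **Polarity truncation.** A subject whose weak N170 cell is actually
   positive cannot yield a positive window *minimum*; the measure
   truncates near zero. With the study-scale spread (cell SD ~2.7 uV)
   around a -0.83 uV mean, an appreciable fraction of simulated subjects
   flips sign, biasing that cell's mean measurement downward by a few
   tenths of a microvolt. Published grand means from extremum measures
   carry the same effect.
3. **Extreme-value noise bias.** Picking an extremum under residual noise
   biases positive components upward and negative components downward, in
   proportion to the residual noise of the subject average.

The bias-focused property test (200 subjects) therefore controls all
three (no jitter, sign-consistent N170 means, moderate noise) to verify
the *machinery* adds no bias of its own, while the study-scale recovery
check (27 subjects, full default conditions, 32-channel montage to keep
average-reference leakage of the P7/P8 bumps small) verifies that each
extracted cell mean lands within two simulation standard errors of the
injected population pattern — the comparison one would make against a
published cell table.

## Problem sizes and numerical choices

The simulation-backed tests use 27 subjects at the full 60-trial paradigm
for the study-scale recovery check, 200 reduced-length subjects for the
bias check, and 200 replicate amplitude cohorts for power (the package's
chosen problem sizes; all complete in a few minutes). Ties in peak
finding go to the earliest sample; epoch windows are half-open; baseline
means vanish to 1e-12 and scalp sums after re-referencing to 1e-9; all
simulators are seed-deterministic and bit-reproducible, which the tests
assert with `identical()`.

## Known limitations

* White (not 1/f) noise; no alpha rhythm, no drifts beyond the filter's
  reach, no muscle artifacts.
* The generator places components only at P7/P8; topographies are
  point-like, so average-reference leakage is slightly pessimistic
  relative to a distributed scalp field.
* No ICA/regression ocular correction — the pipeline rejects, as the
  study did; no latency analysis, no source localisation, no
  sphericity machinery (moot at 2 levels).
* The EDF writer stores the recording as one data record with a 16-bit
  symmetric physical range (resolution ~0.03 uV over +/-1000 uV).
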