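---
title: "Methods: cuffless BP estimation from PPG features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuffless BP estimation from PPG features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The problem and the modelling assumptions

A photoplethysmogram measures blood-volume change under an optical sensor;
its waveform shape carries information about arterial stiffness and wave
reflection, which co-vary with blood pressure. `ppgbp` studies whether a
subject's SBP/DBP can be tracked over a month from 30-second PPG sessions,
given a limited number of cuff calibration readings, and how three modelling
assumptions fare against each other:

* **PLS** — the feature–BP relation is globally linear. Collinearity between
  waveform features (and there is plenty: the band areas and the reflection
  surrogate all respond to the same morphology) is handled by projecting onto
  a few covariance-maximizing latent components rather than inverting an
  ill-conditioned normal matrix.
* **LW-PLS** — the relation is only locally linear. A fresh weighted PLS
  model is fit at every query, with sample weights decaying in Mahalanobis
  distance from the query; distant regimes (different posture, different
  time of month) contribute little.
* **GPR** — the relation is smooth but nonlinear. An RBF kernel with white
  noise on autoscaled features gives the standard closed-form posterior
  mean; the prior pulls predictions toward the calibration mean when the
  query is far from the data.

All three autoscale features and response to zero mean and unit variance on
the current training set ("normalized"/"standardized" variables); every
reported prediction is de-standardized back to mmHg.

## Preprocessing and features

Each session is linearly detrended, low-pass filtered (6th-order Butterworth,
fc = 10 Hz, applied forward and backward so the phase is exactly zero and the
amplitude response is the squared Butterworth magnitude), and detrended
again. Detrending *before* filtering matters numerically: the zero-phase
filter zero-pads the signal, and a nonzero DC level would otherwise produce
large edge transients.

Beats are segmented by peak detection — minimum inter-peak distance
`0.4 * (60 / hr_hint) * fs` samples, prominence at least 0.3 times the robust
signal amplitude (twice the scaled MAD) — with beat feet at the minima
between consecutive peaks; the partial cycles outside the first and last
feet are discarded, so a train of k beats yields k − 2 complete cycles. The
session is represented by its maximally skewed beat (skewness is the
signal-quality index; clean PPG pulses are strongly right-skewed), and the
session is dropped when even that maximum is below 0.1. Skewness is the
population moment coefficient `g1 = m3 / m2^1.5`, not the small-sample
corrected variant, so the 0.1 threshold is unambiguous.

Feature conventions that the method statement leaves open, fixed here:

* **PIR** uses raw (DC-retaining) intensities — an intensity *ratio* is
  meaningless on a detrended zero-mean signal. A minimum-rebased convention
  is available behind `pir_convention = "rebased"` for sensors with an
  arbitrary offset.
* **DTR** takes "end of the waveform" as the last sample of the foot-to-foot
  beat: with the systolic peak at 0-based index k of an N-sample beat,
  `DTR = (N - 1 - k) / (N - 1)`.
* **ri** uses filtered amplitudes rebased to the beat minimum, so the ratio
  is positive and scale-free and `ri >= 1` by construction. The inflection
  point is the largest local maximum of the 5-point-smoothed first derivative
  in the window 10%–90% of the beat length past the systolic peak, falling
  back to the second-derivative zero-crossing nearest the window midpoint
  when the derivative has no interior maximum (reflection-free beats).
* **A02/A25** are areas under the one-sided Fourier *magnitude* spectrum of
  the selected beat, zero-padded to `8 * fs` samples (0.125 Hz bins) and
  integrated by the trapezoidal rule over the half-open bands [0, 2) and
  [2, 5) Hz, so the 2 Hz bin is never counted twice.
* **HR** is the device reading carried by the session record, not re-derived
  from the beat period.

## The synthetic cohort: what it emulates, and what it does not

Month-long paired PPG/cuff datasets are essentially never public, so the
generator is a first-class module. Each beat is a two-Gaussian pulse
(systolic bump + reflected bump on a DC baseline) — the minimal morphology
that exhibits a systolic peak and a downstroke inflection *without* a
dicrotic notch, matching the premise that notch-dependent features are
unreliable. Default widths are 0.08 and 0.11 of the period; wider reflected
bumps flatten the amplitude distribution and push beat skewness below the
SQI threshold, which is exactly the degradation the quality index exists to
catch, so the defaults keep clean beats comfortably above it (worst-case
skewness ≈ 0.3 across the latent range).

Per subject, the generator draws BP intercepts, feature–BP coefficients,
drift slopes, heart-rate distribution and a latent reflection-state
location/scale from population distributions (see `population_defaults()`:
SBP 120 ± 10 mmHg between subjects, HR 70 ± 8 bpm, cuff noise 3 mmHg SD,
drift −0.2 ± 0.05 mmHg/day, values typical of a normotensive adult cohort
measured over one late-spring month). Per session it draws a latent state
(hr, reflection ratio, timing, log-amplitude) and maps it *linearly* to true
BP, plus the slow drift, a 3 mmHg circadian sinusoid peaking late afternoon,
and cuff measurement noise; the noisy value is what the pipeline sees as the
reference. The linear map is deliberate: it makes parameter recovery by PLS
an exact test (predicted MAE should approach the irreducible
`sd * sqrt(2/pi)`), while a flag (`nonlinear = TRUE`) injects a quadratic
heart-rate term to give the nonlinear regressors something to win.
Corrupted sessions (probability 0.02) are rendered as rectified-sine pulses:
still periodic (so segmentation succeeds) but symmetric-to-negatively-skewed
in amplitude, so rejection happens in the SQI stage, where it belongs.

Sessions sit at fixed clock times (07:00, 11:00, 15:00, 19:00), four per day
for 114–118 sessions, giving the ~29-day span the calibration schemes
assume. All randomness flows through one explicit seed; two runs with the
same configuration are byte-identical down to the feature table.

What the generator does **not** emulate: motion artifacts with temporal
structure, respiratory modulation, sensor contact changes, hemodynamic
nonlinearity beyond the optional quadratic term, and any physiologic
coupling between HR and the reflection state. Passing tests therefore show
that the pipeline recovers the structure it assumes — heterogeneous linear
subject maps with slow drift — not that it would attain the same numbers on
clinical data.

## Calibration schemes and the evaluation protocol

Sample indices are 1-based and inclusive, matching the ordinal convention of
the schemes ("15th–18th"). scheme_1 is the single window
`[1, round(0.2 n)]`; scheme_2 is `[1, round(0.04 n)]` plus the five fixed
four-sample windows starting at 15, 35, 55, 75, 95 (windows beyond n are
dropped, an overrunning window is truncated). Round-half-up is used for both
initial windows: it reproduces the canonical counts at n = 115 (23 and 5)
and keeps the calibration fraction within "roughly 20%" (0.18–0.24) for
every n in 100–130, which a ceiling rule does not.

Prediction is *rolling*: a test sample at index i may only be predicted by a
model trained on calibration windows that end before i (for the generalized
strategy, plus all samples of the other subjects — their full datasets, not
just their calibration windows). A fresh model is fit per contiguous test
segment. Test samples with no preceding window are reported unpredictable,
never imputed. Every run carries a leakage audit (max training calibration
index < test index) as an attribute, asserted in the tests.

The generalized strategy is leave-one-subject-out; the alternative
per-sample reading of "leave-one-out" was considered and rejected, since it
would leak the held-out subject's non-calibration samples. The interpolation
baseline — straight lines in sample index between the mean reference BP of
consecutive calibration windows — intentionally uses the *flanking* (hence
partially future) windows: it is a reference-only yardstick for what the
calibration readings alone predict, not a deployable estimator.

Metrics per cell and per subject: MAE, mean error, error SD (n − 1
denominator), RMSE, Pearson r (reported missing, not zero, under zero
variance), Bland–Altman limits `ME ± 1.96 SD`. Pooled rows concatenate test
errors across subjects. Model comparisons use two-sided paired t-tests on
per-subject MAEs with raw p-values — no multiplicity correction, and the
report marks p < 0.05 / p < 0.001.

## Numerical choices

* PLS refuses constant columns and a response orthogonal to the remaining
  features (degenerate component); weights are unit-norm, scores mutually
  orthogonal to 1e-8 by construction.
* The LW-PLS similarity map normalizes distances by their SD
  (`u = exp(-d / (sigma_d * phi))`, default `phi = 1`; `phi = Inf` is exact
  uniform weighting and reduces to global PLS). Degenerate weighted
  components (weight mass collapsed onto coincident samples) stop component
  extraction early, so extreme localization degrades gracefully to the
  nearest-neighbour prediction instead of erroring.
* Covariance inversion for the Mahalanobis metric uses a ridge of
  `1e-8 * trace(S) / P` when ill-conditioned; negative eigenvalues beyond
  tolerance are an error.
* GPR factorizes `K + noise I` by Cholesky with jitter escalation
  (1e-10 → 1e-6). Hyper-parameter refinement maximizes the log marginal
  likelihood by L-BFGS-B in log-space from the stated initial values
  (scale 1, signal 1, noise 1) within [1e-3, 1e3]. The evaluation grid
  defaults to the fixed stated kernel: the generalized cells factorize
  ~1200-sample Gram matrices per segment, and refinement there multiplies
  cost ~100-fold without changing any qualitative comparison; set
  `gpr_optimize = TRUE` to refine in every cell.
* The zero-phase filter's measured amplitude response matches the analytic
  `1 / (1 + (f/10)^12)` to better than 0.01 absolute at 1–20 Hz; the small
  bilinear-transform frequency warping above the cutoff is far below that
  tolerance's passband effect.

## Problem sizes used by the test suite

The acceptance-style checks run at the study's default conditions: five
replicate cohorts of 11 subjects × 114–118 sessions for the
individual-versus-generalized and scheme comparisons, ten 2-subject cohorts
at n = 115 for the PLS noise-floor recovery, and 100-problem sweeps for the
regressor/oracle equivalences. Lighter structural checks (drift recovery,
heterogeneity calibration) use 50 Hz / 10 s sessions, which leave the
reference-BP stream untouched.

## Known limitations

* The skewness SQI is a blunt instrument: it catches flattened or inverted
  morphology but not timing artifacts that preserve amplitude shape.
* `ri` depends on a detectable downstroke inflection; at very low reflection
  amplitude the fallback landmark is a convexity point, which is stable but
  not the same physiologic feature.
* The generalized strategy's poor performance is partly a property of the
  simulated heterogeneity (intercepts not explainable by features); a
  population with feature-identifiable intercepts would narrow the gap.
* Per-subject models trained on 5–25 calibration points estimate the error
  SD noisily; the Bland–Altman limits for early scheme_2 segments should be
  read accordingly.
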