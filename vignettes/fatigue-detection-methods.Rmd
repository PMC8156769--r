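---
title: "Detecting running-induced fatigue from body-worn IMUs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting running-induced fatigue from body-worn IMUs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(runfatigue)
```

## The problem

Running-induced fatigue changes gait: peak tibial and sacral accelerations
tend to rise, hip flexion at initial contact drops, knee flexion extrema
shift, and stride timing becomes more variable. If those changes are large
and consistent enough, a classifier fed with features from body-worn
inertial measurement units (IMUs) can grade a runner's fatigue state — and
the practical question becomes *how few sensors, and where,* still support
reliable detection.

This package implements that analysis as a tested pipeline over a
synthetic cohort that emulates the study protocol: eight runners, each
covering 13 laps of a 400 m track at an individually constant speed, with
three condition segments — laps 2–4 (*no fatigue*), laps 8–10 (*mild
fatigue*), and three post-fatiguing-protocol laps (*heavy fatigue*). The
variable-length fatiguing run between the first and third run is excluded
from analysis and simulated only as a standing gap.

## The synthetic cohort

`generate_session()` builds each session from closed-form, per-stride
waveform templates (sums of periodic Gaussian bumps and sinusoids) for six
sagittal joint angles, eight segmental acceleration magnitudes (split over
three axes by fixed direction cosines), eight pitch angular velocities, and
the sagittal pelvis velocity, sampled at 240 Hz. The templates are not a
musculoskeletal simulation; they are designed to be *segmentable* and to
*carry the named extrema* the feature catalogue measures (knee-extension
minimum at initial contact, mid-stance and mid-swing flexion peaks, impact
spikes, one velocity dip per step).

Choices that matter:

* **Cohort defaults.** Speeds are drawn from a truncated normal around the
  study cohort's printed mean (10.6 ± 1.4 km/h; see
  `runner_characteristics()`); stride times around 0.75 ± 0.05 s. At 12
  km/h and 0.75 s per stride this yields 400/(3.33 × 0.75) ≈ 160 strides
  per lap and side.
* **Fatigue model.** `fatigue_effect_model()` holds per-condition shifts
  for six effect families (peak tibial acceleration +5 %/+10 % at
  mild/heavy, peak sacral acceleration +4 %/+8 %, tibial pitch
  angular-velocity spread +6 %/+14 %, hip flexion at IC −2°/−4°, knee
  flexion extrema +1.5°/+3°, stride-time SD +30 %/+70 %), one global
  `effect_size` scalar, and measurement-noise scales. The study reports no
  quantitative effect sizes of its own, so these defaults are
  literature-inspired magnitudes and deliberately treated as free
  parameters; `effect_size = 0` collapses all three conditions onto one
  generating distribution (the null cohort used in the tests).
* **Fatigue is a smooth function of distance,** not a per-lap step:
  level 0 over laps 1–4, a linear ramp across laps 5–7, level 1 over laps
  8–10 (interpolated between lap midpoints, so the level also drifts
  within a lap), and level 2 throughout the post-protocol run — mirroring
  a gradual rise of perceived exertion.
* **Subject dependence.** Each subject draws per-family effect
  multipliers (SD 0.3 around 1 by default), because fatigue responses are
  strongly subject-dependent; with a large SD, individual subjects can
  flip effect directions.
* **One explicit RNG.** Every generator call takes a named seed; child
  seeds derive deterministically (`derive_seed()`), so the same seed
  reproduces a session bit-for-bit and any subject can be regenerated
  without materializing the cohort.

What the generator does *not* emulate: soft-tissue artefacts, drift,
speed fluctuations within a run, surface/footwear effects, or genuinely
nonstationary fatigue dynamics. Passing tests on this cohort therefore
demonstrate the *pipeline's* correctness and honest subject-level
generalization — not field performance on real recordings.

## Gait segmentation

Following the pipeline's front end (`detect_runs()`, `detect_strides()`,
`detect_initial_contacts()`, `segment_and_normalize()`):

1. **Run bounds** come from zero-crossings of the sagittal pelvis velocity
   around sustained forward motion (smoothed speed above 0.5 m/s for at
   least 2 s).
2. **Stride events** are dominant downward pelvis-velocity peaks. The
   pelvis dips at every step, so candidate minima are gated by prominence
   (0.2 × in-run IQR) and pruned depth-first to a minimum separation of
   0.6 × the stride period, estimated from the autocorrelation of the
   in-run velocity (lag searched between 0.4 and 1.6 s). The 0.6 factor is
   deliberate: the contralateral-step dip sits at almost exactly half a
   stride from its neighbours, so a 0.5 gate would keep or drop it at the
   mercy of timing jitter, while 0.6 rejects it structurally and still
   never collides with true events one full stride apart.
3. **Initial contacts** use the right knee angle: the right IC is the
   knee-extension minimum within ±30 % of a stride around each event; the
   left IC is that landmark offset by half a stride. Knee extension near
   touchdown is the standard landmark; the rule is isolated in one
   function so an alternative (e.g. foot-acceleration spikes) can be
   swapped in. Flat windows, or minima pinned to a window edge, flag the
   stride unusable rather than aborting the session.
4. **Normalization.** Each side's cycle spans consecutive same-side ICs
   (half-open, 1-based) and every curve — 6 joint angles, 8 acceleration
   magnitudes computed as the root-sum-of-squares of the axes, 8 pitch
   angular velocities — is linearly resampled to exactly 150 points.
   Linear interpolation (not splines) keeps the operation monotone,
   endpoint-preserving and easy to verify; a cycle of exactly 150 samples
   round-trips identically. Cycles shorter than 10 samples are dropped.

## The 157-feature catalogue

`feature_catalogue()` enumerates the features with a canonical
segment × quantity × statistic naming scheme: per location, peak
acceleration magnitude and peak pitch angular velocity plus
mean/STD/IQR/skewness/kurtosis of both curves (12 each, 96 total); shock
attenuation `(1 − PSA/PTA) × 100` for each tibia against the pelvis (2);
22 joint-angle event extrema (knee 5 per side, ankle and hip 3 per side);
3 IC-event left-minus-right symmetry features; 30 joint-angle statistics;
and stride time/length per side (4). Totals: 43 biomechanical + 110
statistical + 4 spatiotemporal = 157.

Numerical conventions, chosen where the analysis leaves them open:

* **Event windows** (fraction of the cycle, 0 = IC): IC 0–5 %, mid-stance
  5–35 %, toe-off 30–45 %, mid-swing 50–75 %, end-swing 85–100 %. Events
  are windowed extrema — maxima for flexion-type events, minima where the
  event is an extension (knee IC, toe-off, end swing; hip toe-off; ankle
  toe-off). The windows follow standard running gait phases and live in
  one overridable table (`joint_event_windows()`).
* **Statistics**: sample SD, type-7 IQR, sample skewness `m3/m2^1.5` and
  excess kurtosis `m4/m2^2 − 3`, with skewness and kurtosis defined as 0
  for zero-variance input so degenerate cycles propagate zeros rather
  than NaN.
* **Stride length** uses the nominal (controlled) lap speed times stride
  time rather than integrated pelvis velocity — the protocol controls
  speed, and integration would add drift without adding information.
* **Shock attenuation** uses the percent form; peaks of zero yield a
  missing value rather than an error.
* **Feature attribution.** Each catalogue entry records which sensors it
  needs, so configurations act as column masks over one full-sensor
  extraction. The spatiotemporal features are attributed to the
  segmentation chain that measures them — pelvis velocity (L2) for stride
  events plus right thigh/tibia (L3, L5) for the right-knee IC landmark —
  which keeps every single-IMU mask at exactly 12 features, as the study
  design requires. Extraction itself always runs on the full recording.

## Smoothing, labeling, normalization

All features are smoothed with a causal 400 m (one-lap) moving average
over cumulative distance: row *i* becomes the mean of rows within
`(d_i − 400, d_i]`, and rows with less than one full lap of history are
dropped. The window is applied per subject *and per run*: distance is
contiguous across recorded laps, but the fatiguing run sits between runs
1 and 3, so a window spanning the gap would blend pre- and post-protocol
gait. A consequence of the drop rule is that the first post-protocol lap
carries no smoothed rows, leaving the heavy class with two laps per
subject (the classes are therefore mildly imbalanced, ~3:3:2). A causal
window matches the real-time framing (detection delayed by one lap); a
centred window is available via the same operator.

Labeled rows (laps 2–4 → *no fatigue*, 8–10 → *mild*, post-protocol laps →
*heavy*; everything else excluded) are then z-scored per subject —
features, like tibial acceleration, scale with speed, and each subject
runs at their own pace. Whether to smooth before or after z-scoring is not
dictated by the analysis; the default is smooth-then-z-score, and
`prepare_feature_table(order = "zscore_first")` provides the other order
(both are exercised in the tests; since z-scoring is affine per subject
and the smoother is linear, the two differ only through the drop rule).
Computing the normalization over labeled rows only keeps all
cross-validation folds consistent, at the price of a mild, label-blind
distributional coupling between folds of the same subject — a known
limitation inherent to per-subject normalization.

## Evaluation

`nested_loso_evaluate()` enforces subject-level honesty: after one-lap
smoothing, stride rows within a subject are strongly autocorrelated, so
random row-level splits would leak; the only data splits anywhere are by
subject. The outer loop holds each subject out for testing; the inner loop
excludes one further validation subject at a time, fits a 100-tree random
forest on the rest, and records out-of-bag permutation importances (mean
over trees of the OOB accuracy drop when one feature's values are
permuted; the forests and importances are computed by `ranger`, pinned to
single-threaded, seeded fits). Inner-fold importances are averaged
arithmetically, the top 12 features are selected (ties broken by canonical
catalogue order; masks of ≤ 12 features — the single-sensor case — pass
through whole), the final forest is retrained on all training subjects,
and the held-out subject is scored. Forest hyperparameters beyond the tree
count stay at the library defaults. Confusion matrices accumulate over
folds; sensitivity, specificity, precision and F1 are one-vs-rest with
precision 0 (and a warning) for never-predicted classes, and headline
accuracy is reported as mean ± SD over folds.

Seeds derive per fold from the master seed, so any fold is reproducible in
isolation. Selection lists per fold feed a frequency-based feature ranking
(`ranked_feature_table()`).

## Problem sizes and expected behaviour

The test-suite and acceptance runs use the full protocol scale — 8
subjects × 13 laps × 400 m at 240 Hz, roughly 1 450 smoothed labeled rows
per subject — with the left-thigh + left-tibia (L4+L6, 34 candidate
features) configuration as the evaluation workhorse; the analysis drivers
additionally evaluate one representative configuration per category up to
the whole body. Two cohort-level properties anchor the statistics: a
zero-effect cohort must score at chance (accuracy within [0.25, 0.42]
around 1/3) and a strong-effect cohort (effect size 4, homogeneous
subjects, class separations ≥ 3 within-class SDs) must exceed 0.9. Between
those anchors, absolute accuracies on synthetic cohorts depend entirely on
the assumed effect sizes and say nothing quantitative about real
recordings — reproducing the study's real-data accuracies would require
the deposited dataset, which this package does not consume.

## Known limitations

* Waveform realism is limited to what the feature set measures; features
  sensitive to waveform shape beyond the planted structure (e.g. skewness
  of acceleration) carry no fatigue signal by construction.
* Initial-contact detection leans on a sharp knee-extension landmark; on
  real data the ±30 % window and the half-stride left-IC offset would need
  validation against force-plate or foot-switch ground truth.
* Per-subject z-scoring uses labeled rows only (see above).
* The generator's between-subject variability is stylized (multipliers on
  shared templates); real cohorts vary in waveform shape, not just scale.
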