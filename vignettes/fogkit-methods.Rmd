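---
title: "Detecting freezing of gait from body-worn inertial sensors"
author: "fogkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting freezing of gait from body-worn inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogkit)
```

## The problem

Freezing of gait (FoG) is an intermittent inability to initiate or maintain
locomotion in Parkinson's disease. Episodes range from sub-second hesitations
to arrests of tens of seconds and are a major cause of falls. Clinical
assessment relies on questionnaires and on video rating of laboratory walking
protocols; both miss what happens during ordinary daily life. Body-worn
inertial measurement units (IMUs) on the feet and lumbar region make
continuous home monitoring possible, provided a transparent algorithm can
turn the raw signals into freezing outcomes.

`fogkit` implements such a detector, threshold-based and auditable, together
with the aggregation, turning and evaluation machinery needed to run a
week-long monitoring study end to end, and a synthetic-signal generator so
that every stage can be validated against known ground truth without patient
data.

## The detector

Detection operates on 1-s non-overlapping windows inside *walking bouts* and
combines two per-window criteria, both of which must fire:

1. **Bilateral decorrelation.** During regular walking the left and right
   medio-lateral (sagittal-plane) foot angular velocities are strongly
   correlated; the correlation collapses before and during freezing. A
   window is a potential freeze when the Pearson correlation of the two
   medio-lateral gyroscope traces falls below `corr_threshold = 0.5`. A
   zero-variance window (a motionless foot mid-bout, consistent with an
   akinetic arrest) leaves the correlation undefined; it is treated as a
   potential freeze and the decision is left to the second criterion.

2. **Freeze ratio.** Trembling during freezing concentrates accelerometer
   energy above the locomotor band. For each foot the antero-posterior
   acceleration window is mean-removed and Fourier-transformed; the freeze
   ratio is the energy in the high band (3, 10] Hz over the energy in the
   low band (0, 3] Hz. A window is a potential freeze when the ratio exceeds
   `ratio_threshold = 10`. The two feet are combined by taking the larger
   ratio (configurable: `max`, `mean`, or per-foot `either`), the most
   sensitive monotone choice given that trembling can be asymmetric.

Runs of flagged windows become freezing segments; segments separated by
hesitations of at most `merge_gap_s = 2` s are merged into one episode whose
duration spans from first start to last end (hesitation time included).
Episodes are then binned into the clinical duration categories: very short,
short (2–5 s), long (> 5 s). The clinical bins leave 1–2 s unassigned and
are finer than the detector's 1-s resolution, so the package uses the
exhaustive order-preserving completion: single-window episodes are
`very_short`, 2–5 s inclusive `short`, above 5 s `long`.

### Numerical choices

* Windows start at the bout's first sample; a trailing fraction shorter than
  one window is dropped. At 128 Hz a 1-s window gives exact integer-Hz bins,
  so band boundary assignment matters: bands are half-open `(lo, hi]` and
  the 3-Hz bin belongs to the low band.
* The DC bin is always excluded — the antero-posterior accelerometer carries
  a gravity component whose DC energy would otherwise crush the ratio.
* The low-band energy is guarded as `max(E_low, 1e-12 * E_total)` so that a
  pure-tremor window (zero locomotor energy) still produces a finite ratio
  far above any threshold, and an all-zero window is defined to have ratio 0.
* Indexing is 0-based and half-open everywhere, so windows, bouts and
  episodes tile without off-by-one ambiguity.

### Walking-bout gating

The detector only runs inside walking bouts of at least 10 s (inclusive
boundary), detected from the lumbar sensor per 30-min analysis window. The
bout detector is a documented stand-in, not a reimplementation of any
published bout detector: the lumbar gyroscope magnitude is band-passed to
the locomotor band (0.5–3 Hz), a centered 2-s moving RMS forms an activity
envelope, and hysteresis thresholding (`on_threshold`, `off_threshold`)
with bridging of rest gaps shorter than 2 s yields the walking mask. The
hysteresis defaults (5 and 2.5 °/s) are calibrated once against the
synthetic generator's amplitude scale — roughly the geometric midpoint
between the generator's rest floor (≈ 0.7 °/s in-band RMS) and its walking
level (≈ 10 °/s) — and are expected to need re-tuning for real hardware;
all bout parameters are exposed in `bout_params()`.

## Outcome measures

Per 30-min window, the freezing outcome is the percentage of walking time
spent frozen: total episode time over total bout time, times 100. In
daily-life mode very short episodes are excluded from freezing time (their
single-second duration proved unreliable even between human raters);
laboratory mode (`include_very_short = TRUE`) keeps them. Windows without
walking have an undefined percentage and are excluded from aggregation
rather than counted as 0% — the outcome is conditional on walking, and
counting rest windows as zero would dilute it (this is an interpretation,
and it is configurable by filtering the summary table).

Weekly aggregation reports both the cumulative sum of per-window
percentages and their mean (the mean is the headline, the cumulative sum is
`mean × n` and is reported alongside), plus the coefficient of variation
(sample SD over mean, over windows with walking) and the episode-category
composition. A subject's freezer score is the mean fraction of walking time
spent frozen; the default classification threshold 0.09 corresponds to the
published operating point against a clinical rater.

## Turning features

Turns are detected from the low-pass-filtered (1.5 Hz) lumbar yaw rate: a
candidate is a contiguous same-sign excursion reaching 15 °/s, extended to
the surrounding zero crossings; its angle is the trapezoidal integral of
the yaw rate. Only the 15 °/s criterion is inherited from the published
description; the completions — minimum angle 45°, zero-crossing extension,
merging of same-direction fragments separated by under 0.1 s — are standard
for lumbar-yaw turn detectors and are configurable, not claims about the
original implementation. Per window the package reports turn count, mean
angle, mean duration, mean peak velocity and the CV of peak velocity.

## The synthetic-signal generator

The generator produces the statistical structure the detector relies on,
*not* biomechanically faithful gait — its purpose is falsifiable testing of
the detection chain, and passing tests on it says nothing about accuracy on
real patients:

* **Walking**: a common locomotor waveform (harmonic series at the stride
  frequency, kept inside 0.5–3 Hz, unit RMS) drives both feet, giving
  bilateral correlation near 1; antero-posterior accelerometers receive
  locomotor-band content.
* **Freezing**: the locomotor component is suppressed to 10% and
  band-limited trembling (default 3.5–9.5 Hz) with independent left/right
  realizations is injected into the foot gyroscopes and accelerometers.
  Trembling noise is synthesized in the frequency domain so its spectrum is
  exactly zero outside the band; a filtered-noise skirt would leak energy
  into the locomotor band and corrupt the freeze ratio by construction. The
  gyroscope trembling carries an extra independent broadband component
  (jerky, non-rhythmic movement): pure narrowband noise over 1 s has so few
  degrees of freedom that chance bilateral correlations above 0.5 would be
  common, which is a property of narrowband processes, not of the detector.
* **Rest**: white sensor noise plus low-frequency (0.5–2.5 Hz) postural
  sway on the accelerometers. The sway anchors the low band so that the
  freeze ratio of a rest window is well below threshold.
* **Turns**: raised-cosine yaw pulses whose integral equals the scheduled
  angle.
* **Scale conventions**: amplitudes are expressed in accelerometer units
  (m/s²) with a fixed 50 (°/s)/(m/s²) gyroscope scale. Defaults — locomotor
  2 m/s², tremor 3 m/s², noise SD 0.1 m/s², sway 0.3 m/s² — give foot
  angular rates of ±100 °/s and freeze ratios around 30–70 during
  trembling, both in the range reported for instrumented gait. The freeze
  ratio exceeds 10 when `tremor_amp / locomotor_amp` is above roughly 0.4;
  the default ratio of 1.5 leaves a wide margin.

Lumbar locomotor activity follows the *walking segment* schedule, including
freezing seconds: freezing happens inside a walking bout, and the bout gate
must stay open across it. This is a simplification — real trunk movement
during an arrest is reduced, and a real bout detector may fragment bouts
around long freezes.

What the generator does **not** emulate: akinetic (non-trembling) freezing,
festination, stride-to-stride variability, soft tissue artifacts, sensor
drift or changes of sensor orientation. Detection of akinetic freezing is a
known limitation of the freeze-ratio approach itself.

At the detector's 1-s resolution, episode boundary windows that straddle a
scheduled transition are flagged only when the trembling covers most of the
window, so detected episodes are typically trimmed by up to one second per
edge; interior single-window misses are absorbed by hesitation merging.
This is why cohort-level recovery of the scheduled freezing burden is
accurate to well under one percentage point while individual boundaries
carry ±1 s uncertainty.

## Evaluation statistics

`icc_2_1()` implements the two-way random-effects, single-measure,
absolute-agreement intraclass correlation from the ANOVA mean squares,

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the standard F-based 95% confidence interval. Agreement strength is
labelled negligible / weak / moderate / strong / very strong at cut points
0.2, 0.4, 0.7, 0.9; the published cut points are ambiguous at the
boundaries, and the package fixes the left-closed convention (so 0.4 is
"moderate", 0.9 is "very strong") to match the "< 0.2 negligible" anchor.
A perfect-agreement matrix makes the interval formula degenerate and the
interval is reported as the point value.

`roc_analysis()` builds the empirical ROC curve (via pROC) with trapezoidal
AUC — equal to the normalized Mann–Whitney statistic — and selects the
operating threshold by Youden's J; the published tables report a "best
threshold" without stating the criterion, and Youden's J is the standard
choice (ties resolve to the lower threshold; classification is strictly
above threshold). Confusion metrics are computed directly from the scores
at that threshold.

## Problem sizes used in validation

The test suite and the acceptance script validate on deliberately compact
synthetic designs: multi-day subjects use 600-s days containing two 200-s
walking segments, cohorts use 15–20 subjects, and scheduled freezing
fractions span 0–0.2 of walking time with episodes of 10–25 s separated by
at least 3 s (so that detected episodes cannot merge across schedule gaps).
These sizes are the package's own validation design; all generators scale
linearly if longer recordings are wanted.

## Known limitations

* The bout detector is a calibrated stand-in; on real data the original
  pipeline's bout segmentation may differ, which shifts the walking-time
  denominator of every percentage.
* Very short (single-window) episodes are detector-resolution artifacts as
  much as clinical events; they are excluded from daily-life freezing time
  by default.
* The detector is non-causal only through the bout envelope; it is not a
  real-time implementation and makes no latency guarantees.
* Thresholds (0.5, 10) were tuned at 128 Hz; recordings at other rates are
  polyphase-resampled to 128 Hz on load rather than re-tuning the
  thresholds.
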