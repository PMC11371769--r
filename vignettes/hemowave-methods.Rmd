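---
title: "Arterial-waveform prediction of blood loss: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arterial-waveform prediction of blood loss: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemowave)
```

## The problem

Mean arterial pressure (MAP) is the bedside gold standard for recognising
hemorrhagic shock, but compensatory mechanisms hold MAP near baseline until
a large fraction of blood volume is already lost. The arterial pressure
*waveform*, in contrast, reshapes continuously as volume is withdrawn:
pulse pressure narrows, heart rate climbs, upstroke and decay timings
shift. `hemowave` implements a beat-level feature-extraction and
decision-tree pipeline that exploits this: it segments a continuous
arterial recording into beats, computes a large registry of per-beat
features, and trains bagged regression trees to track three blood-loss
metrics, so that hemorrhage can be detected minutes earlier than by
watching MAP.

The canine controlled-hemorrhage protocol the package is organised around
has three phases: a baseline recording; venous blood withdrawal over at
most one hour, terminated when MAP enters a 35–50 mmHg target window or
when 40% of the estimated blood volume (80 mL/kg body weight) has been
shed, whichever comes first; and a 45-minute shock hold at the final shed
volume. Resuscitation is out of scope.

## The prediction targets

All three targets are functions of the cumulative shed volume
$V(t)$ (mL) and are aligned to beat timestamps by previous-value (step)
interpolation, which never anticipates blood not yet shed.

**BLVM** (blood loss volume metric), on a 0–1 scale relative to the
study's total shed volume $V_\mathrm{tot}$:

$$\mathrm{BLVM}(t) = 1 - \frac{V(t)}{V_\mathrm{tot}}$$

over baseline and hemorrhage; during the shock hold BLVM is 0 by
definition (maximal hemorrhage volume is maintained with no active
hemorrhage).

**PEBL** (percent estimated blood loss), relative to the estimated blood
volume so it transfers across animals:

$$\mathrm{PEBL}(t) = \frac{V(t)}{80\ \mathrm{mL/kg} \times \mathrm{weight\ (kg)}}$$

**HemArea**, a volume–duration burden that keeps growing while an animal
remains hypovolemic, computed from a BLVM series as a rectangle-rule sum

$$\mathrm{HemArea}(t_k) = \sum_{i \le k} \lvert \mathrm{BLVM}(t_i) - 1 \rvert\, \Delta t_i,
\qquad \Delta t_i = t_i - t_{i-1},$$

with the first slice using the first available step. Because the quadrature
convention is genuinely open we chose left rectangles, matching the
integral-slice picture of the metric; the ground-truth variant
(`hemarea_ground_truth()`) integrates $V(t)$ directly in mL·s. Direct
tree-based prediction of HemArea is supported (`direct_hemarea = TRUE`)
but the recommended path derives it from the BLVM predictions, which is
dramatically more accurate because integration averages away beat-level
prediction noise.

## Preprocessing and beat landmarks

Recordings are read from plain-text `time_s,pressure_mmhg` tables with a
four-marker sidecar (baseline start, hemorrhage start/end, hold end). A
Hamming windowed-sinc FIR lowpass (default 25 Hz cutoff, 251 taps at
500 Hz, scaled with sample rate) with reflect padding and symmetric
alignment removes line noise without shifting landmarks; the half-filter
edge regions are excluded from beat detection. The cutoff and order are
package defaults — they preserve beat morphology to roughly the 12th
harmonic at canine heart rates — and are exposed in the configuration.
Integer-factor downsampling (e.g. 1 kHz to 500 Hz) applies an anti-alias
filter first.

Beat segmentation detects systolic peaks first (prominence-based, with a
0.25 s spacing floor, i.e. a 240 bpm ceiling above canine tachycardia),
then locates each pulse foot between successive peaks. Because the
diastolic run can be flat to within the noise, the raw window minimum is
ill-posed; the foot is instead anchored on the upstroke as the last
lightly-smoothed sample at or below 5% of the window amplitude above the
window minimum. This choice is stable under repeated filtering because the
upstroke lies well inside the passband.

Within each foot-to-foot segment five fiducials are located: foot,
half-rise (first crossing of half the foot-to-peak amplitude), systolic
peak (segment maximum), first inflection, and segment end (the next foot).
The inflection detector looks for the first *persisted* concave-then-convex
transition of a 5-point Savitzky–Golay second derivative strictly after the
peak, with three numerical guards that discretisation forces on the ideal
rule:

* a post-peak refractory (default 24 ms) skips the concave cap that
  lowpass filtering smears over a sharp notch-free peak;
* runs must exceed 12% of the post-peak curvature scale, so filter ringing
  is not mistaken for curvature;
* the last quarter of the segment is excluded, since the next foot's
  corner always produces a terminal curvature sign change — under an
  unrestricted literal scan *every* sampled beat would have an
  "inflection" and the fallback would be unreachable.

When no inflection is found, the half-drop fallback places the landmark at
the first post-peak sample at or below
`peak + half_drop_fraction * (next_foot - peak)`. The fraction defaults to
0.5 (the midpoint) and is exposed as a tunable, because where the dicrotic
landmark should sit when it cannot be observed is physiologically
ambiguous. Every valid beat has either a true inflection or the fallback —
never neither — and downstream features treat the two identically.

With heavy sample noise the decay's small curvature becomes
noise-dominated and inflection/fallback discrimination degrades; the
fallback fraction is logged per run so this is visible. On noiseless
analytic beats the discrimination is exact, which is what the test suite
pins down.

## The feature registry

The exact 1,901-feature list of the original MATLAB implementation is not
reproducible from public material, so the registry is an openly documented
family expansion over the same feature classes — durations, magnitude
differences, variability — with a deterministic count:

* 11 durations (every ordered landmark pair, plus the RR interval),
* 10 amplitudes and 10 slopes over the same pairs,
* 4 trapezoidal areas above the foot-value baseline
  (foot–peak, peak–inflection, inflection–end, foot–end),
* 4 pressure scalars (MAP, systolic, diastolic, pulse pressure),
* 39 × 38 = 1,482 ordered pairwise ratios of the 39 base features
  (denominators below 1e−9 in magnitude yield 0 so every feature is
  finite),
* 39 × 5 × 3 = 585 rolling statistics (mean, SD, RMS of successive
  differences, min, max over trailing windows of 5, 15 and 30 beats),

for a default total of 2,106 ≥ 1,900 features. Rolling windows are
*trailing* with shrinking windows over the first beats, never centered:
the motivating use case is real-time monitoring, so no feature may peek
forward, and truncating a record never changes earlier rows. The pipeline
default excludes the ratio family (624 features): at cohort scale those
1,482 columns dominate memory while adding little for tree models, and
the full registry remains one configuration flag away.

## Models

Features are ranked per fold by greedy minimum-redundancy
maximum-relevance (MRMR, difference scheme): the first feature maximises
mutual information with the target, each next feature maximises relevance
minus mean MI against the already-selected set. MI is estimated by
equal-frequency 10-bin discretisation; ties break by registry order, so
ranking is deterministic. The regressor is a bagged ensemble of CART
trees (bootstrap resamples, no complexity pruning, minimum leaf size from
the grid). The hyperparameter grid is 3 feature counts {5, 10, 20} × 4
leaf sizes {4, 8, 12, 16} = 12 models per metric. One source note: the
protocol we follow describes both "bagged" trees and a single learner;
since bagging with one learner degenerates to a single tree we default to
30 learners and expose `n_learners = 1` as the documented single-tree
mode.

Validation is leave-one-subject-out (LOSO): for each of the 6 subjects,
MRMR ranking *and* model fitting use only the other subjects' pooled
beats, and all 5 replicates of the held-out subject are predicted blind —
30 blind datasets in the reference cohort. Ranking is recomputed inside
each fold; computing it once on all data would leak the held-out subject
into selection. Predictions are smoothed with a 500-point centered moving
mean (clipped shrinking windows at the edges); "points" are prediction
samples, i.e. beats. Scores (regression R², RMSE, and RMSE normalised by
the ground-truth range) are averaged over replicates within subject, then
across subjects. The headline R² is the regression R² of predictions on
ground truth; the coefficient of determination is also computed and
labelled separately.

## Detection latency

For comparability across datasets of different durations, each predictor
series is linearly interpolated onto 100 equally spaced points per study
region (baseline | hemorrhage | hold). The detection threshold is the 25th
percentile of the 100 baseline points for falling metrics (BLVM, MAP) and
the 75th for rising ones (PEBL, HemArea); comparisons are strict, so a
flat baseline equal to its own percentile cannot self-trigger. Hemorrhage
is declared at the first run of five consecutive positive points after
baseline; the reported time is the *onset* of the run (its completion is
also returned), converted to minutes after hemorrhage start through the
region's real duration. A series that never produces such a run yields an
infinite sentinel; summary means censor it at the end of the hold and
report the number of detections. ROC analysis uses the first 200
normalized points (baseline vs hemorrhage); AUROC is the tie-aware
rank statistic, auto-oriented so informative predictors score above 0.5,
with the orientation recorded. The MAP comparator enters raw (per-beat
means), not smoothed: it is a measurement, not a model output.

## The synthetic cohort

The study's canine dataset is access-restricted, so the package carries a
simulator whose role is to push known signal through every stage, not to
be a validated canine hemodynamics model (no baroreflex, no
resuscitation). Each beat is an analytic template: a diastolic level plus
two Gaussian waves (systolic, and a smaller delayed dicrotic wave that
guarantees one post-systolic inflection), with the diastolic level solved
so the beat mean equals the commanded MAP. A configuration switch replaces
the template with a squared-sine upstroke and convex exponential decay —
no persisted post-systolic concave region — to exercise the half-drop
fallback. Waveform morphology parameters (wave widths and timings) are
plausible placeholders, not fitted canine values.

The hemodynamic response to loss fraction $f$ is the minimal monotone
model consistent with the protocol's stop rules:
$\mathrm{MAP}(f) = 90 - 110f$, $\mathrm{PP}(f) = 40(1 - 0.5f)$,
$\mathrm{HR}(f) = 90(1 + 0.5f)$, so MAP reaches the 35–50 mmHg window near
$f \approx 0.36$–0.4. On top of this the simulator adds slow baseline
variability — a vasomotor-type MAP sinusoid (4 mmHg amplitude, 70 s
period) plus an AR(1) drift (1.5 mmHg stationary SD, 120 s time constant),
with smaller relative variation on pulse pressure (2%) and heart rate
(2 bpm) — i.i.d. Gaussian sample noise (1 mmHg), and log-normal per-beat
RR jitter (2%). The baseline variability matters scientifically: it is
what makes raw MAP a *late* detector, exactly as compensation does in a
real animal; without it a clean linear MAP would cross its own baseline
percentile almost immediately and the comparison to feature-based metrics
would be meaningless. These parameters were fixed from physiological
plausibility for anesthetized dogs and are not tuned.

Cohorts draw subject-level physiology once per subject (weight uniform
18–30 kg, baseline MAP/HR/PP normal around the defaults) and share it
across that subject's replicates; replicates differ in noise streams and a
±10% hemorrhage-rate jitter. Every random stream derives its seed from
the master seed and the (subject, replicate) key, so identical
configurations are bit-identical.

**What passing on this cohort does and does not show.** The simulated
feature–loss relation is smooth, monotone and low-dimensional, so blind
LOSO R² values here (≈0.99) are far above what heterogeneous real animals
would produce, and detection latencies are shorter. Passing
demonstrates that the pipeline recovers known signal blindly across
subjects, that derived HemArea is far more accurate than beat-level
prediction, and that the detection-latency ordering
HemArea ≤ PEBL ≤ MAP emerges — the qualitative structure, not the
published numbers, which cannot be reproduced without the restricted
data.

### Problem sizes

The reference "desk-scale" cohort used by the test suite and the
acceptance script compresses the protocol to 5 min baseline, hemorrhage
at 60 mL/min (reaching its stop condition within ~10 min), and a 5 min
hold at 250 Hz — about 66,000 beats across 30 records — with the
624-feature configuration and 30-learner ensembles. These sizes were
chosen so a full run completes in minutes on one core while still
spanning all three phases with thousands of beats per record; the full
protocol durations and 500 Hz rate remain available through
`sim_config()`.

## Numerical conventions and degenerate inputs

* Time is 0-based seconds; index ranges are half-open `[start, end)`; the
  next foot belongs to the next beat.
* Step interpolation for volumes (never inventing volume), linear
  interpolation for region normalization.
* A study with zero total shed volume has no defined BLVM (error); a
  constant prediction target makes MRMR relevance undefined (error);
  beats with non-positive pulse amplitude are marked invalid, dropped
  from the feature matrix, and counted in the run log.
* The robust regression audit (`robust_fit()`) always reports ordinary
  least squares and triggers a bisquare IRLS refit when more than 1% of
  studentized residuals exceed |3|, returning the final weights.
* Hemorrhage termination is computed analytically from the linear
  response model, so the volume-stop example (640 mL at 20 kg) is exact
  rather than rounded to a beat boundary.

## Known limitations

* The simulator's beat morphology and response slopes are placeholders;
  nothing here validates against measured canine waveforms.
* Inflection detection under heavy noise degrades toward the fallback
  path; the per-run fallback fraction makes this observable.
* The registry emulates the documented feature classes but cannot match
  the original 1,901 definitions item-by-item.
* Rational-ratio resampling, ECG channels, arrhythmia handling and the
  resuscitation phase are out of scope.
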