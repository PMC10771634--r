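---
title: "Quantifying the Timed Up and Go test from skeletal tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the Timed Up and Go test from skeletal tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The Timed Up and Go (TUG) test is a standard clinical mobility assessment:
the subject rises from a chair, walks 3 m, turns, walks back and sits down.
Clinics usually record only the total stopwatch time, but the test contains
five distinct subtasks — sit-to-stand, walk out, turning, walk back,
stand-to-sit — each informative about balance and gait. Markerless depth
cameras of the Kinect V.2 class track 25 body joints at 20 frames/second,
which is enough to segment those subtasks and compute a rich spatiotemporal
gait profile without body-worn sensors. Profiles of this kind separate
older adults with Alzheimer's disease (AD) from healthy controls (HC):
AD gait is slower, shorter-stepped, with longer transfers, longer turns and
more double-support time.

`tugait` implements the full chain: a documented on-disk recording format,
low-pass preprocessing with automated quality screening, subtask
segmentation, a 61-feature profile, covariate-adjusted feature selection,
and SVM classification under five-fold and leave-one-subject-out
cross-validation. Because clinical TUG recordings of this kind are not
publicly deposited, the package also contains a first-class synthetic
recording generator with exact ground truth; every downstream stage is
validated against it.

## The recording model

A recording is a `[frames x 25 joints x 3]` array of camera-space positions
in meters: x lateral, y vertical (up), z depth increasing away from the
camera. The camera faces the walkway, so z decreases on the way out and
increases on the way back. Timestamps are `frame / frame_rate`; frames are
indexed from 0 in all on-disk formats and reported segments. The joint
vocabulary is the Kinect V.2 skeleton; the "shoulder center" of the gait
literature is `SpineShoulder` and the hip center is `SpineBase`.

Two dialects are supported: long CSV (`frame,joint,x,y,z` plus a JSON
metadata sidecar) and a self-contained JSON object. Both round-trip to at
least 6 significant digits. Frames with missing joints are format errors,
not imputation targets: occluded recordings should be excluded, not
repaired.

## The synthetic generator

`generate_recording()` animates a skeleton through the five phases:

* a seated plateau (1 s lead-in/lead-out),
* a rise driven by a trunk-flexion arc (peak pitch 40 degrees) combined
  with hip elevation, which reproduces the canonical shoulder-center
  height curve — a dip below the seated level followed by the climb to the
  standing plateau — and its mirror image when sitting down;
* straight walking with alternating feet: foot contacts advance by one
  step length, swings follow half-cosine profiles, stance occupies 55% of
  the gait cycle so that each contact retains double support;
* an in-place turn along a semicircular arc of radius 0.25 m that rotates
  the shoulder axis, collapsing the lateral inter-shoulder distance to
  near zero mid-turn.

Group profiles carry the magnitudes reported for instrumented TUG in
older cohorts: `hc_profile()` uses gait speed 0.57 m/s, step length 40 cm,
turning 2.29 s, age 68.5 +/- 2.6 y, GDS 1.2; `ad_profile()` uses 0.34 m/s,
31 cm, 5.75 s, age 75.8 +/- 7.2 y, GDS 6.3. `generate_cohort()` draws
per-subject profiles with lognormal multipliers (log-SD 0.15, matching the
~19% between-subject CV of gait speed in such cohorts) and draws age/GDS
from the group distributions, so kinematic group differences arrive
confounded with age and depression score, as in real data.

Three reconciliations were needed where published summary tables are not
mutually consistent:

* Speed, step length and cadence are linked by `v = L * cadence / 60`, but
  printed group means do not satisfy it (0.57 m/s and 40 cm imply ~85
  steps/min, not the printed ~66). The generator honors **speed and step
  length**; cadence is derived. Supplying `cadence_steps_per_min` instead
  re-derives step length from speed and cadence.
* The number of steps per 3-m leg must be an integer, so nominal step
  length is rescaled (by up to ~7%) to fit the walkway; ground truth
  records the realized values.
* Left/right asymmetry scales the left step length and time by
  `1 - asymmetry` with the stride preserved, so the designed step symmetry
  index is exactly `1 - asymmetry` (default 0.25, matching symmetry
  indices near 0.75 in such cohorts).

Sensor noise is i.i.d. Gaussian per joint-axis-frame (default SD 5 mm),
added before any filtering. The generator does **not** model occlusion,
re-identification failures, arm swing, or biomechanically accurate joint
torques; passing tests demonstrate correctness of the signal-processing
chain on plausibly-shaped signals, not robustness to every Kinect failure
mode.

## Preprocessing

All 75 joint-axis series pass through a 6th-order Butterworth low-pass at
3 Hz, applied forward and backward. The zero-phase application is a
deliberate design choice: all boundary detections are time measurements,
and a causal filter would delay every event by the group delay. Both ends
are extended by odd-reflection padding sized from the filter's slowest
pole (about 130 samples at the default design) so the start-up transient
decays below 1e-11 before the retained samples; shorter, fixed-length
padding leaves millimeter-scale end transients that corrupt the seated
plateaus.

Quality screening automates the visual rejection of noisy recordings:
a recording fails if the discrete derivative of the filtered right-ankle
depth signal exceeds 3 m/s anywhere. Elderly TUG gait keeps ankle speeds
well below that, so surviving excursions indicate tracking artifacts. Under
the default between-subject dispersion the screen also rejects the fastest
few percent of synthetic walkers whose swing peaks brush the threshold —
accepted behavior, reported per subject in the pipeline's attrition table.
The threshold is exposed (`qc_threshold`).

## Segmentation

Plateaus of the shoulder-center height are frames whose smoothed height
derivative stays below 0.05 m/s for at least 0.5 s. Sit-to-stand runs from
the last seated-plateau frame to the first standing-plateau frame;
stand-to-sit mirrors it. Because a smooth transfer leaves its plateau with
near-zero velocity, any velocity threshold is crossed late; boundaries are
therefore refined with a displacement model: the deviation from the
plateau level grows quadratically in time, so the crossing times `t1`,
`t2` of two thresholds in ratio 4 (12 mm and 48 mm) give the onset as
`t0 = 2 t1 - t2`. The inner crossing is anchored to the same flank as the
outer one, which makes the estimate immune to the small overshoot bumps
the zero-phase filter leaves next to a plateau.

Turning is detected from the lateral inter-shoulder distance. With a
near-constant turning rate the distance follows `W |cos(pi (t - t0) / T)|`,
so the two crossings of half the walking median sit at exactly one third
and two thirds of the turn; the segment is extrapolated from the
(sub-frame, linearly interpolated) crossing times. This assumes the
rotation proceeds at a roughly constant rate — true for the generator and
approximately true for real turns; a strongly paused turn would be
underestimated.

The two walking segments are the spans between the transfers and the turn,
so the five segments are ordered, non-overlapping, and tile the test
exactly. All boundaries are half-open `[start, end)` in frames, which
makes subtask durations sum without double counting. On 100 default-profile
recordings, all ten boundaries land within 0.25 s of ground truth
(median error 0.05 s); slower AD-profile transfers recover within 0.25 s in
about 95% of recordings.

## Gait events and the 61 features

Within the walking segments, stance frames are those where the central
difference of the foot depth signal stays below 0.08 m/s for at least
0.1 s; sub-0.15 s threshold re-crossings (filter ringing around heel
strike) are bridged before short islands are cleaned up. Steps are the
local peaks of the sagittal inter-foot distance, gated by a 0.45 s minimum
spacing so a noisy double-support plateau cannot yield two peaks; the peak
search extends 0.3 s past the segment end because the final contact of
each leg lands on the walking/turn boundary. Gait cycles pair consecutive
same-foot stance onsets; single support is the contralateral swing within
the cycle and double support the overlap of both stances.

The profile comprises exactly 61 named features: the total TUG duration;
duration and (magnitude of) vertical shoulder-center velocity for both
transfers; turning duration and velocity; walking duration; gait velocity;
mean/variability/median triples for 16 step and stride quantities; and
step/stride counts and per-minute frequencies. Variability is the
coefficient of variation `SD / mean * 100`. Symmetry and regularity use the
similarity index `SI = 1 - |xR - xL| / max(xR, xL)`, computed with an
absolute difference so the index is bounded by 1 regardless of operand
order; symmetry pairs the right and left steps of one stride, regularity
pairs consecutive same-foot strides. Step width (lateral inter-foot
distance at the step peak) and step height (swing-apex foot elevation above
its stance baseline) are defined here, since the feature names alone do
not pin them down. Turning velocity is the horizontal path speed of the
hip center during the turn, consistent with its m/s units. Step and stride
statistics pool both walking legs, matching the single printed value per
feature; 54 of the 61 features derive from the walking subtask.

## Covariate adjustment and selection

Each feature is adjusted by ANCOVA: a least-squares fit of
`feature ~ group + age + gds` on the fitting subset, after which the
covariate contribution is re-centered at the pooled covariate means.
Fitting **with** the group term keeps group signal out of the covariate
slopes; adjusting already-adjusted values is a no-op. Constant covariates
contribute slope 0; a covariate perfectly aliased with group makes
adjustment unidentifiable and errors.

Each feature is tested with Student's t if Shapiro-Wilk finds both groups
normal (p >= 0.05 in both — a conservative gate), otherwise Mann-Whitney U.
Significance is p < 0.05 with no multiple-testing correction — a faithful
but liberal choice, so the significant set should be read as a screen, not
as a family-wise claim. Among significant features, pairs with |Pearson r|
> 0.90 are pruned by visiting features in ascending p-order (ties broken
by canonical column order) and dropping any that correlate too strongly
with an already-kept one; the procedure is deterministic and invariant to
column order. Spearman correlation is available via `corr_method`.

## Classification

A support vector machine with linear and Gaussian RBF kernels, `C` and
`gamma` grid-searched over powers of two from 2^-4 to 2^4. Features are
standardized by training-fold statistics — without this, a shared grid
across features spanning seconds, centimeters and percent is meaningless.
Within each outer training fold (stratified five-fold with seeded
shuffling, or leave-one-subject-out), adjustment, selection and
standardization are re-fit on the training subjects only, and
hyper-parameters are chosen by 3-fold inner cross-validation (ties go to
the earlier grid row: linear before RBF, smaller C, smaller gamma). This
nesting costs accuracy relative to selecting once on all data but avoids
optimistic bias; the unnested variant is available with `nested = FALSE`.
If a training fold yields no significant feature (possible under
null-like data), the single lowest-p feature is used so the fold can still
be scored. Metrics with zero denominators are reported as `NA`, never
coerced to 0. Five-fold results aggregate as mean +/- SD over folds; LOSO
pools all held-out predictions.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: the
analytic Butterworth magnitude response (agreement within 2%), exhaustive
enumeration of the Mann-Whitney distribution at n <= 6, closed-form
checks of the duration/velocity/CoV/SI formulas, and the generator's
ground truth for segmentation (100 recordings), gait-event and parameter
recovery (50 recordings, median relative error ~2%, bound 10%), ANCOVA
effect recovery (200 simulations), null calibration of the selection
stage, a mutation test proving held-out subjects cannot influence
training-fold selection, and an end-to-end 30/30 cohort at the printed
group magnitudes that must classify at >= 90% (observed ~98% five-fold).
These sizes keep the whole suite under a few minutes on one CPU while
leaving comfortable statistical margins.

## Known limitations

* The generator's motion is acceleration-limited, not strictly
  band-limited: the 3 Hz filter rounds movement corners by up to ~15 mm,
  so "filtering changes nothing" holds only away from corners.
* Steps whose distance peak falls exactly on the walking/turn boundary are
  recovered by the 0.3 s search extension, but their timing inherits the
  boundary uncertainty.
* The turn is modeled and detected as a single continuous rotation;
  multi-pause turns and multi-turn TUG variants are out of scope.
* Transfer vertical velocities are stored as magnitudes; the sign is
  recoverable from the segment labels.
* Real-cohort accuracies cannot be reproduced without the original
  recordings; the synthetic cohort demonstrates pipeline validity, not
  clinical performance.
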