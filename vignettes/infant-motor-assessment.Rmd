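---
title: "Automated infant gross-motor assessment from skeletal keypoint sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated infant gross-motor assessment from skeletal keypoint sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Gross-motor developmental delay in infants aged roughly 2–6 months is
usually screened during clinical visits, where unfamiliar surroundings can
suppress an infant's spontaneous movement. An alternative is to record the
infant at home, lying supine and moving freely, run a pose-estimation
network over the video, and assess development from the resulting skeletal
time series. `infantmotion` implements the downstream half of that idea:
everything that happens *after* pose estimation, from raw per-frame
17-keypoint detections (COCO layout: nose, eyes, ears, shoulders, elbows,
wrists, hips, knees, ankles, each with x, y and a confidence score at a
nominal 15 fps) to a cross-validated binary classification of typical
versus delayed development, plus the standard keypoint-evaluation metrics
(OKS, mAP, mAR) used to qualify the upstream pose model.

No real infant recordings ship with the package. A seeded synthetic motion
simulator stands in for them, which makes every stage testable and every
number in this vignette reproducible from code.

## Preprocessing model

Raw detections are noisy in two distinct ways — outright failures
(occluded limbs, confused left/right assignments) and frame-to-frame
jitter — and they live in camera coordinates that differ across
recordings. The pipeline addresses each in turn:

1. **Confidence gate.** Keypoints with confidence strictly below 0.5 are
   marked missing. The inequality is strict: a keypoint at exactly the
   threshold is kept. The threshold is configurable
   (`default_config()$conf_threshold`).
2. **Gap filling.** Each keypoint's x and y tracks are filled by linear
   interpolation between the nearest visible neighbours. Leading and
   trailing gaps are filled by nearest-value extension rather than
   extrapolation, which would manufacture motion at clip boundaries.
   Interpolated points get confidence equal to the gate threshold so that
   re-filtering is a no-op. A track that is never visible cannot be
   reconstructed; the sequence is rejected (and listed under `exclusions`
   by `run_end_to_end()`) rather than zero-filled, because a fabricated
   static joint would bias every speed feature downward — exactly the
   direction that mimics the delayed class.
3. **Smoothing.** A centered rolling mean of five frames (≈0.33 s at
   15 fps) suppresses detection jitter before any differentiation. At the
   sequence edges the window is truncated to the available frames, so a
   15 s clip keeps exactly 225 frames. Smoothing runs in pixel space,
   before rotation, so that per-frame rotation jitter is damped rather
   than amplified.
4. **Trunk normalization.** Per frame, the skeleton is translated so the
   shoulder midpoint is at the origin, rotated (properly, preserving
   left/right) so the trunk vector — shoulder midpoint to hip midpoint —
   points along +y, and divided by that frame's trunk length. All
   downstream quantities are therefore in trunk lengths and invariant to
   camera distance, position and roll. Rotation is per frame (so a
   wriggling trunk never reintroduces apparent limb motion); a zero trunk
   length is a degenerate frame and an error.

The package tests verify the resulting invariance directly: the 227
features of a noiseless simulated clip change by less than 1e-6 under 100
random global rotation/translation/scaling transforms of the raw pixels.

## Clips and the activity gate

Normalized sequences are cut into non-overlapping 15 s clips (225 frames);
a trailing remainder is dropped. For each clip the mean movement speed is
computed: the mean over frames and over the eight distal joints (elbows,
wrists, knees, ankles) of the forward-difference speed, in trunk
lengths/s. Shoulders and hips are anchors of the normalization and are
excluded. Only clips with mean speed strictly greater than
0.9 trunk-lengths/s qualify for feature extraction — quiescent or sleeping
segments carry little gross-motor information. The running (cumulative)
mean is available via `cumulative_mean_speed()` for reporting.

Velocities use forward differences with the final frame's velocity copied
from its predecessor. This keeps every per-frame series at clip length and
makes constant-velocity test cases exact (0.06 trunk lengths per frame at
15 fps gives exactly 0.9 trunk-lengths/s).

## The 227-feature catalog

Features are computed per clip, never pooled across clips. The catalog
(`feature_catalog()`, also shipped as
`inst/extdata/feature_catalog.json`) is the package's normative
definition, organised by category:

| category | count |
|---|---|
| distal-joint speed mean + max (8 joints) | 16 |
| distal-joint acceleration mean + max | 16 |
| distal-joint speed entropy | 8 |
| distal-joint acceleration entropy | 8 |
| limb-segment angular velocity mean + max | 16 |
| limb-segment angular acceleration mean + max | 16 |
| 8 joint angles × {mean, max, min, std, range} | 40 |
| 8 joint angular velocities × {mean, max, std} | 24 |
| 8 joint angular accelerations × {mean, max, std} | 24 |
| pairwise windowed speed correlations, C(8,2) pairs | 28 |
| pairwise windowed acceleration correlations | 28 |
| whole-body speed mean, acceleration mean, speed entropy | 3 |

Definitional choices that were genuinely open:

* **Joint angles** (shoulders, elbows, hips, knees, both sides) are
  interior angles in [0°, 180°]: shoulder = trunk line vs upper arm
  (rays from the shoulder to the hip midpoint and to the elbow), elbow =
  upper arm vs forearm, hip = trunk line vs thigh, knee = thigh vs shank.
  A zero-length ray (coincident keypoints) carries the previous frame's
  angle forward.
* **Segment angular velocity** attaches an angular quantity to joints
  that have no interior angle of their own (wrists, ankles): the rate of
  change of the orientation of the limb segment *ending* at the joint
  (forearm for the wrist, upper arm for the elbow, thigh for the knee,
  shank for the ankle), computed from wrapped angle differences so the
  series never jumps across ±180°, in degrees/s.
* **Magnitude semantics.** Angular velocity/acceleration summaries use
  the absolute rate, matching the speed features (a limb oscillating
  symmetrically should not average to zero).
* **Entropy** is Shannon entropy (nats) of the empirical distribution
  over 10 equal-width bins spanning the clip's own [min, max]; a constant
  series has entropy 0 and the maximum is ln 10 ≈ 2.303. Binning on the
  clip's own range keeps the feature scale-free.
* **Windowed correlation** is the mean Pearson correlation over all
  sliding 5-frame windows of a pair of per-joint speed (or acceleration)
  series. Windows where either series is constant are skipped —
  correlation is undefined there — and a pair with no valid window scores
  0. Near-constant series (shoulder and hip speeds after normalization)
  are guarded by an absolute variance floor (window sd below 1e-10
  trunk-lengths/s counts as constant) so the statistic never amplifies
  floating-point residue. When the window spans the whole series the
  statistic reduces to the ordinary Pearson correlation, which is how it
  is tested.

Every feature is finite for every valid clip, and the count is 227
independent of clip content.

## Feature screening and classification

Each feature is screened by a classic one-way ANOVA across the two label
groups (`stats::oneway.test` with equal variances); features with
p < 0.05 are retained. With two groups the F statistic is exactly the
squared pooled-variance two-sample t statistic, which the test suite
verifies on 1000 random datasets to 1e-9 relative error. No multiplicity
correction is applied at selection time (the screening is deliberately
permissive); Benjamini–Hochberg-adjusted p values are attached for
inspection.

Class imbalance is handled by oversampling the minority class by seeded
duplication with replacement; when the target is an exact multiple of the
minority size (the canonical 26 → 78 case) every row is replicated the
same number of times. Features are then standardized to zero mean and
unit variance using the population (divide-by-n) standard deviation —
the convention of the usual machine-learning scalers — with zero-variance
columns mapped to 0.

Four classifiers are evaluated by seeded stratified 5-fold
cross-validation: random forest (`randomForest`), XGBoost (`xgboost`,
100 rounds, binary logistic objective), SVM (`e1071`, RBF kernel with
probability estimates) and logistic regression (`stats::glm`). No
hyperparameter search is performed; each toolkit's defaults are used.
Reported metrics are accuracy, recall, precision, F1 and AUC, aggregated
two ways: support-weighted over the two classes (the headline numbers)
and macro, with per-fold detail retained. For a binary task the two
one-vs-rest AUCs coincide, so the weighted AUC equals the ROC AUC of the
delayed-class probability (`pROC`).

### Stage ordering and leakage

`run_pipeline()` supports two orderings. The default applies screening,
oversampling and standardization to the full table *before* splitting
into folds. This is the conventional ordering in this application area,
but it leaks: duplicated minority rows span fold boundaries, and
selection has seen the held-out labels. The `leakage_safe = TRUE` variant
fits all three steps inside each training fold only and applies them
frozen to the held-out fold; its metrics are the ones that estimate
generalization. Both modes run in the test suite. The null-calibration
test (below) uses the leakage-safe mode, because chance-level behaviour
is a property only of a leakage-free procedure.

A further caveat both modes share: if several clips come from the same
infant, folds should be split by subject, not by clip. The pipeline
splits by row and makes no subject-level claim.

## Keypoint evaluation (OKS, mAP, mAR)

For qualifying an upstream pose model, the package implements object
keypoint similarity:

OKS = Σᵢ exp(−dᵢ² / (2 s² kᵢ²)) δ(vᵢ > 0) / Σᵢ δ(vᵢ > 0)

with dᵢ the Euclidean distance between predicted and ground-truth
keypoint i, s the object scale, kᵢ the per-keypoint tolerance (defaulting
to the canonical MS-COCO sigmas, `coco_sigmas`) and vᵢ the ground-truth
visibility. Two conventions for s circulate — the square root of the
annotated box area (the COCO convention, our default) and the raw pixel
area; `keypoint_eval_case(scale_is_area = TRUE)` supports the latter, and
either way the formula uses s² exactly as written. In the single-infant,
one-prediction-per-instance regime a case is a true positive at threshold
t iff OKS ≥ t, so precision equals recall at every threshold and
mAP = mAR = the mean matched fraction over thresholds 0.50, 0.55, …,
0.95. Multi-instance matching is out of scope.

## The synthetic motion simulator

`simulate_sequence()` drives a rigid-trunk supine skeleton (trunk
length 1, anatomical left at +x) whose four limbs are two-segment
kinematic chains. Each segment's orientation oscillates as a seeded sum
of two sinusoids (fundamental plus a half-weight 1.7× harmonic). Two
motion components are superposed:

* **class oscillators** — per-subject amplitude drawn from 1.0–1.4 rad
  and fundamental frequency from 0.9–1.3 Hz, the carrier of the class
  effect;
* a **baseline fidgety component** (0.5 rad, 1.2–1.8 Hz) present
  identically in both classes.

The delayed class multiplies the class-oscillator amplitudes by 0.4 and
frequencies by 0.6 (a hypokinesia proxy) and mixes a shared left/right
oscillator into each limb pair with weight 0.6, raising bilateral
coupling. The direction of these effects is a documented modeling choice,
not a claim about infants. The class-independent baseline reflects that a
clip-level cohort is assembled from *active* clips: even hypokinetic
subjects exhibit baseline movement, and with these defaults both classes
clear the 0.9 trunk-lengths/s gate (typical ≈ 2.3, delayed ≈ 1.1
trunk-lengths/s) while remaining strongly separable. Setting the three
effect parameters to (1, 1, 0) yields an exact null in which the label is
independent of every feature.

After the kinematics, each subject gets a random camera (rotation in
(−π, π], 150–300 pixels per trunk length, translation), Gaussian keypoint
jitter (sd 0.01 trunk lengths), i.i.d. per-keypoint-frame dropout
(probability 0.02) and low-confidence corruption (probability 0.03, with
inflated positional error) — so simulated cohorts continuously exercise
the confidence gate, interpolation and normalization invariance. A single
integer seed determines everything, using R's fixed default generator.

What the simulator does *not* emulate: biomechanically valid joint
limits, trunk articulation, rolling or prone postures, bursty occlusion
(available as an option, off by default), camera perspective
(the transform is a similarity, not a homography) and pose-estimator
error structure (left/right swaps, correlated misses). Passing tests on
simulated cohorts therefore demonstrate that the machinery is correct and
calibrated, not that the classifier transfers to real infants.

## Calibration experiments

Two cohort-level experiments are run routinely by the test suite and by
`scripts/acceptance.R`, each on cohorts of 83 typical and 26 delayed
subjects contributing one 15 s clip each (the clip-level cohort shape of
the modeling task):

* **Null calibration.** Twenty independent zero-effect cohorts,
  leakage-safe cross-validation, metrics averaged over the four
  classifiers. Because the test folds are imbalanced 83:26, the raw
  accuracy of a label-independent classifier is governed by its majority
  bias — any value between 0.24 and 0.76 is consistent with zero signal —
  so chance is assessed on the balanced-accuracy (macro recall) scale,
  whose null expectation is exactly 0.5 for any prediction bias. The
  pooled balanced accuracy is required to lie in the central 95% binomial
  band around 0.5 (observed ≈ 0.50).
* **Effect recovery.** One default-effect cohort through the full
  pipeline (default full-table stage ordering, pinned seed); the random-forest
  support-weighted F1 must reach at least 0.9. With the default effect
  sizes the classes are in fact separated essentially perfectly —
  the synthetic effect is deliberately strong, and this check is a
  qualitative sanity bound, not a benchmark claim.

A related small-sample caveat the suite documents: under a permutation
null, cross-validated accuracy sits *slightly below* 0.5 on average,
because the training and held-out group differences of a finite dataset
are anti-correlated. The tests therefore check that permuted-label
accuracy lies in the chance band, not that it equals 0.5 exactly.

## Numerical and degenerate-input policy

* Rolling means and windowed correlations use exact cumulative-sum
  arithmetic (tested against `zoo::rollapply` and per-window
  `stats::cor` respectively).
* Angle computations clamp cosines to [−1, 1] before `acos`; zero-length
  rays carry the previous frame's angle (first frame falls back to 180°).
* A keypoint track visible in zero frames, a zero trunk length, a
  smoothing window longer than the sequence, an unknown classifier id, a
  fold missing a class, and an OKS case with no visible keypoint are all
  errors by design, raised with the offending subject/frame named.
* Sequences shorter than one clip yield an empty clip list, not an error.

## Problem sizes

Routine runs in this package use 15 s sequences (one clip per subject),
cohorts of 83 + 26 subjects, 20 seeds for the null study, 1000-case
random suites for the OKS and ANOVA oracle checks and 100 random
transforms for the invariance check. These sizes give stable estimates
(binomial half-widths near two percentage points on pooled rates) while a
full check of the package completes in minutes on a laptop.
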