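---
title: "Methods: gait and posture classification from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait and posture classification from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

People recovering from stroke move differently at home than in the clinic.
Quantifying *what* they do all day — lying, sitting, standing, walking,
climbing stairs — from body-worn inertial sensors gives clinicians an
objective picture of real-life mobility. `imugait` implements a complete
window-based activity-recognition pipeline for this setting: five sensor
locations (chest, both wrists, both ankles), each recording tri-axial
acceleration, tri-axial angular rate and barometric altitude at 50 Hz,
with per-sample ground-truth labels over five activity/posture classes and
three transition classes (lying↔sit, sit↔stand, stand↔walk, undirected).

Two classification tasks are supported:

* **gait** — binary: walking and stair walking aggregate to `gait`; the
  three postures to `no_gait`;
* **gait_posture** — 5-class: lying, sitting, standing, walking, stairs.

## Pipeline

### Signal decomposition

Each raw sensor stream is decomposed into four channels:

* **posture acceleration** — zero-phase order-2 Butterworth low-pass at
  0.5 Hz: the gravity/orientation component;
* **activity acceleration** — zero-phase order-2 band-pass 0.5–11 Hz: the
  voluntary-movement band;
* **filtered gyroscope** — zero-phase order-2 low-pass at 11 Hz;
* **filtered altitude** — 0.5-s moving-median despiker (removing the
  altimeter's 0.1 m quantization steps) followed by the 0.5 Hz low-pass.

The 0.5 Hz posture/activity split and the 11 Hz upper movement bound are
standard choices in human activity recognition: body postures change slower
than ~0.5 Hz while voluntary movement carries little energy above ~10 Hz.
All cutoffs live in one config block (`preprocess_defaults()`) and can be
overridden; results are expected to be robust to moderate (±50%) cutoff
changes, though this is not asserted by the test suite.

Numerical details that matter: filters are applied forward–backward
(zero phase, so window features are not skewed by group delay), with the
channel mean removed first (scaled by the cascade's DC gain on re-addition,
so constant inputs are reproduced exactly) and odd (point-symmetric) edge
extension of six filter lengths (so altitude ramps pass the session
boundaries without endpoint droop). The first and last second of a session
remain influenced by boundary extension; the `filtered_channels` object
flags them via its `edge_samples` attribute.

### Windowing

Channels and labels are segmented into 128-sample windows (2.56 s at
50 Hz) with 64-sample hop (50% overlap); a trailing partial window is
discarded, since the feature contract requires fixed-length windows. Each
window takes the **majority label** of its samples; exact ties break to
the label whose first occurrence in the window is earliest — deterministic
and order-stable. A window whose majority label is a transition class
carries its undirected adjoining pair (taken from the class name, e.g.
`trans_sit_stand` → sitting, standing).

### Features

Each sensor contributes **134 features per window**. For each tri-axial
channel (posture acceleration, activity acceleration, gyroscope), 13
per-axis statistics — mean, variance, min, max, range, median,
interquartile range, RMS, skewness, kurtosis, spectral energy, spectral
entropy, dominant frequency — plus the 3 pairwise inter-axis correlation
coefficients: 42 per channel, 126 per sensor. The barometric channel adds
8: mean, variance, min, max, range, least-squares slope (m/s), net change
(last − first) and RMS of first differences. Spectral features use the
magnitude spectrum of the Hann-tapered, unpadded 128-sample window;
dominant frequency excludes the DC bin (resolution 50/128 ≈ 0.39 Hz).
Correlation against a constant axis is defined as 0. The registry
(`feature_registry()`) is one machine-readable table, so the set can be
amended without touching pipeline code. With all five sensors the feature
vector has 670 dimensions.

### Per-subject standardization

Each feature is standardized within subject:
$\tilde x_j^{(i)} = (x_j^{(i)} - \mu_j)/\sigma_j$ with $\mu_j$ the
per-subject mean and $\sigma_j$ the **population** (1/n) standard
deviation; degenerate features ($\sigma_j = 0$) map to 0. This makes every
feature's magnitude relative to the subject's own repertoire, removing
between-subject offsets (device placement, body size). Statistics are
computed over **all** of a subject's windows, not only training windows:
because normalization never crosses subjects, it leaks no information in
leave-one-subject-out evaluation.

### Classifiers and hyperparameter grids

Three models are available, with the grids explored by the inner
cross-validation loop:

| model | grid | points |
|---|---|---|
| SVM (RBF kernel, class-balanced) | C ∈ {0.01, 0.1, 1, 10} | 4 |
| logistic regression (elastic net, intercept, class-balanced) | C ∈ {0.001, 0.01, 0.1} × l1 ratio ∈ {0.01, 0.1} | 6 |
| kNN | n ∈ {1, 2, 4, 8, 12, 16, 20, 24, 28, 32} × weights ∈ {uniform, distance} | 20 |

Class-balanced weighting means weights proportional to inverse class
frequency, $n/(k\,n_c)$. The SVM uses `e1071` (libsvm) with the default
RBF width $\gamma = 1/d$ — equivalent to the common "scale" heuristic
$1/(d\,\mathrm{Var})$ here, because features are standardized to unit
variance. Logistic regression uses `glmnet` with
$\lambda = 1/(C\,n)$ and $\alpha$ = l1 ratio, which makes the penalized
objective match the C/l1-ratio parameterization common in other toolkits.
kNN is a small exact implementation (Euclidean distances; distance
weighting as $1/\max(d, 10^{-12})$; vote ties break to the first class in
declared order).

The `reduced` grid keeps only the first entry of every parameter list —
one point per model — for quick demonstrations and continuous testing.

### Transition-aware nested leave-one-subject-out evaluation

Transition windows are removed from every **training** set but kept in
every **evaluation** set: models never learn transitions, yet are scored
on recordings that contain them, as real life does. A transition window
between adjoining classes A and B counts as correct if the model predicts
either A or B (mapped through the task's label aggregation). Two literal
consequences under the binary gait task: a `trans_stand_walk` window
(pair no_gait/gait) is always correct, and a `trans_sit_stand` or
`trans_lying_sit` window is correct only when `no_gait` is predicted.

Evaluation is a **nested leave-one-subject-out** (LOSO): the outer loop
holds out each subject; the inner loop runs LOSO over the remaining
subjects, fitting every grid point on each inner training set and scoring
balanced accuracy — with transitions included — on the inner test subject.
The grid point with the best unweighted mean across inner folds (ties →
earliest point in declared grid order) is refitted on the whole outer
training set and scored on the held-out subject. A runtime assertion
verifies that no window of the held-out subject enters any fit. Inner
aggregation is mean-of-fold-scores (subjects weighted equally regardless
of window counts), consistent with per-subject reporting throughout;
pooled-window scoring would up-weight long recordings.

Metrics are one-vs-rest sensitivity, specificity and PPV per class,
overall accuracy (fraction of transition-aware-correct windows), and
balanced accuracy. Per class, balanced accuracy is
(sensitivity + specificity)/2; the overall value is the unweighted
(macro) mean over classes, which reduces to the familiar binary definition
for the gait task. The binary definition is the one the evaluation
protocol anchors on; the macro extension for the 5-class task is this
package's choice and is isolated in one function. For confusion matrices,
a correctly scored transition window is credited to the predicted class;
an incorrect one to the first element of its adjoining pair (after
windowing the sub-window label layout is gone, so "the closer adjoining
class" is not recoverable; the first-of-pair rule is deterministic and the
raw counts are retained so either convention can be recomputed). Pooled
confusion matrices sum counts over folds and row-normalize to 100%;
empty true-class rows are reported as `NA`, not 0.

Per-subject performance can be related to clinical impairment scores
(Berg Balance Scale, 10-m walk speed, ...) with
`correlate_performance_impairment()`: Pearson when both variables pass
Shapiro–Wilk normality at α = 0.05, Spearman otherwise; two-sided p-values,
no multiple-testing correction (raw p-values are reported as such).

## The synthetic cohort

Real home recordings of post-stroke subjects are not redistributable, so
the package ships a generator whose output has the statistical structure
the classifier exploits:

* **postures** differ by a per-sensor gravity orientation (unit vector ×
  9.81 m/s²) plus sensor noise. Wrist orientations for sitting and
  standing are deliberately identical up to per-subject variability (arms
  rest similarly in both), making sitting-vs-standing the hardest
  confusion for wrist-only configurations — ankle and chest orientations
  do distinguish them;
* **gait** adds cadence-locked oscillation (fundamental + one harmonic,
  per-subject cadence ~0.65–0.95 strides/s) to ankle, wrist and chest
  channels; the affected side's limb amplitudes are scaled by an
  attenuation factor in [0.2, 0.8], emulating hemiparetic asymmetry;
* **stairs** use a slower stride (step-over-step vs step-by-step profile
  flag) and ramp the shared altitude channel by 0.17 m per step
  (alternating ascent/descent across bouts), with the altimeter's 0.1 m
  quantization applied after noise;
* **transitions** interpolate the gravity orientation spherically over
  durations of 4.0 s (lying↔sit), 2.7 s (sit↔stand) and 4.7 s
  (stand↔walk), carved symmetrically out of the adjoining bouts, and ramp
  the gait envelope.

`build_daily_script()` constructs each session's bout sequence so the
emitted label track reproduces the free-living class-time distribution
the pipeline is calibrated against — lying 4.8%, sitting 20.2%, standing
32.8%, walking 19.5%, stairs 6.5%, remainder transitions — exactly at the
continuous level for any session length (bout-duration jitter is
renormalized within class). Bout counts scale with session length;
transition durations are fixed at their class means, and total session
time absorbs the small rounding mismatch among the printed shares.

**Problem sizes.** The default cohort is 14 subjects × 5-minute sessions
(~230 windows/subject, ~3,100 windows in all). Five minutes is a
compressed daily-life script, chosen so a full nested-LOSO experiment
with the 670-dimensional SVM completes in minutes on a single core; class
shares are length-invariant by construction, and classification accuracy
is insensitive to session length well below this size. Sessions of any
length can be requested via `session_s`.

**What passing tests do not show.** The generator contains no free-living
confounders (elevators, vehicles), no voluntary upper-limb activity during
gait (grasping, gesticulating — the main cause of wrist-only errors in
real data), no non-stationary sensor placement drift, and gait is
sinusoidal rather than biomechanical. Performance numbers on synthetic
cohorts therefore demonstrate that the pipeline's machinery is correct and
that its qualitative structure (ankle information helps; transitions do
not break scoring) holds — they are not estimates of accuracy on clinical
data.

## Reproducibility

All generators take explicit integer seeds (`default_seed()` = 20220926);
identical inputs and seeds yield bit-identical sessions, datasets and
evaluation reports. `run_pipeline()` caches stage outputs by a content
hash of their inputs, writes the fully resolved configuration alongside
results, and rejects configurations with unknown keys before execution.
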