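---
title: "Graphomotor feature extraction and screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphomotor feature extraction and screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphomotor)
```

## The problem

Developmental dysgraphia is a neuro-motor disorder that impairs
handwriting in roughly 5–10% of school-aged children. The reference
diagnostic instruments are text-copying tests, which require two years of
writing practice and are language-specific. Drawing tasks — graphomotor
tests — probe the same fine-motor control without requiring any writing
ability, so a screening tool built on them can reach younger children and
transfer across languages.

`graphomotor` implements the complete analysis chain for such a tool:
ingestion of digitizing-tablet pen recordings of six standard drawing
tasks, extraction of a fixed inventory of 345 kinematic and geometric
features, age-windowed standardization, and a leakage-safe
feature-selection + classification evaluation protocol. Because clinical
recordings are sensitive medical data and rarely shareable, the package
also contains a first-class drawing simulator that generates
template-faithful synthetic cohorts with controllable impairment, so
every stage is testable end to end.

## Data model

A *recording* is one child's trajectory for one stimulus: a 200 Hz time
series of pen position (x rightward, y upward, millimetres; tablet counts
are converted at 0.25 mm/count), pen height `z` (tracked up to 10 mm
above the surface) and a boolean on-paper flag. The flag is authoritative:
a *stroke* is a maximal run of pen-down samples, a *lift* a pen-up run
strictly between two strokes. Indices are 1-based and inclusive, the
native R convention. Recordings whose timestamp jitter exceeds 10% of the
nominal 5 ms interval are linearly resampled onto the uniform grid, since
every kinematic formula assumes uniform sampling. Gaps in in-air tracking
are treated as pen-up samples with linearly interpolated positions.

The six stimuli are: **Circuit 1** (three parallel horizontal lines,
thick to thin), **Circuit 2** (a labyrinth of 5 long and 4 short parts
joined by eight right-angle corners), **Circuit 3** (an oval),
**Shapes 1** (vertical, horizontal and sloping lines plus a circle),
**Shapes 2** (triangle, plus sign, square, diagonal cross) and **The
Loops** (two series of six alternated cursive loops, three up and three
down per series). Template geometries are package constants at a
plausible school-workbook scale (the originals are pictures, not
coordinate lists) and ship as a JSON asset
(`inst/extdata/templates.json`) that users may replace with their own
geometry in the same schema.

## Preprocessing

Coordinates are low-pass filtered with a fourth-order Butterworth filter
at 15 Hz before any feature is computed: tablet noise sits above that
band while the useful handwriting band is around 5 Hz. Two decisions are
ours where the filter family and cutoff alone were given:

* **Zero-phase (forward–backward) filtering.** A single causal pass
  delays the trajectory by the group delay, which would bias every
  geometric feature; two passes cancel the phase. The effective
  magnitude response is the squared single-pass response, i.e. −6 dB at
  the cutoff.
* **Per-stroke filtering.** Filtering across a lift would smooth over an
  artificial discontinuity (the pen jumped while in the air), bleeding
  it into both flanking strokes.

The implementation reflects the signal around its end points with a long
pad before filtering (and filters around the series mean), because
`signal::filtfilt` starts from a zero filter state; without the pad the
startup transient would corrupt the first ~0.5 s of each stroke. DC gain
is exactly 1.

Derivatives (velocity, acceleration, jerk) use central differences on
the uniform grid with one-sided differences at stroke end points.
Strokes shorter than 4 samples are skipped by kinematic aggregates.

## The feature inventory

The registry (`feature_registry()`) fixes 345 features: 47 *general*
features per stimulus and 63 *specific* ones (Circuit 1: 17, Circuit 2:
9, Circuit 3: 5, Shapes 1: 12, Shapes 2: 12, The Loops: 8). The exact
composition of the 47 is a package decision (the inventory groups are
fixed, their full enumeration was not): stroke/lift timing statistics
(10), kinematic aggregates including low-velocity paths, velocity
quartet, average normalized jerk, abnormal stops, velocity peaks and
SNvpd (13), trajectory SNR on x and y (2), global and per-stroke order-2
Rényi entropy (3 + 6), and per-axis path statistics with in-air
counterparts (13). The registry is asserted in tests and is the single
source of truth for canonical feature order, which also defines all
tie-breaks downstream.

Notable definitions:

* **Order-2 Rényi entropy** `RE2 = -log Σ p²` (natural log) of the step
  distribution: interior sample *i* gets weight proportional to its
  displacement from sample *i − 1*, normalized to sum 1. Strictly
  uniform movement gives the uniform distribution, hence maximal
  entropy; zero total displacement is defined as uniform. Per-stroke
  values are computed on strokes translated to their centroid and
  isotropically scaled to a unit bounding box (isotropic, so stroke
  shape is preserved), for x, y and the 2-D trajectory alike.
* **Trajectory SNR** compares a coordinate series with its smoothed
  version (order-2 Butterworth at 5 Hz, zero-phase):
  `10·log10(P_smooth / P_residual)` dB, capped at ±120 dB (the cap
  engages when residual power falls below 1e-12 of signal power). Quick
  unexpected movements land in the residual.
* **Average normalized jerk**
  `sqrt(0.5 ∫ jerk² dt · T⁵ / L²)`, per stroke, duration-weighted across
  strokes — invariant to uniform time and space rescaling. For the
  minimum-jerk quintic point-to-point profile the value is
  `sqrt(360) ≈ 18.97`, which the tests verify against numeric
  quadrature of the closed form.
* **SNvpd** is implemented as velocity peaks per centimetre of pen-down
  path; its source definition is not reproduced in the literature we
  build on, so this reading is flagged as an interpretation.
* **Velocity peaks** are local speed maxima with prominence ≥ 10% of the
  maximum speed and ≥ 50 ms separation — thresholds chosen to ignore
  sensor ripple at 200 Hz, since no peak criterion was given.
* **Low-velocity paths**: a sample is low-velocity when net displacement
  over a centered 150 ms window is under 1 mm. Windows stay full-length
  near stroke ends (shifted, not truncated), so slow steady motion is
  not flagged at the edges. **Abnormal stops** are low-velocity runs
  ≥ 150 ms that do not touch the first or last 50 ms of the stroke
  (start/stop transients).

Specific features anchor the drawing to the template: vertical-residual
MSE for Circuit 1's horizontal lines, generalized to perpendicular
residuals for Circuit 2's slanted parts and Circuit 3's oval (for
horizontal lines the perpendicular form reduces exactly to the printed
vertical one); per-line stroke counts, backtracking, and completion
before the first lift; parallelism as the standard deviation of
regression slopes (Circuit 2 regresses the perpendicular offset on the
along-part coordinate in each part's local frame, so "slope" is
orientation-free); turn quality `1 − ⟨v_b, v_a⟩` with directions from
total-least-squares fits over 5 mm of path on each side of the captured
corner (10 mm capture radius, corners with fewer than 5 usable samples
on a side are skipped); direction changes counted on a 4-quadrant
heading quantization (boundaries at 45° + k·90°, 15° hysteresis, 50 ms
minimum run — one ideal oval traversal gives exactly 4); the
oval-adapted entropy applies the Gaussian radial weights
`exp(−(d − r)²/200)` (mm², renormalized to a proper distribution — the
printed density values alone do not sum to 1) before the entropy;
Shapes 1's index of curvature is drawn-line path length over summed
template chord length (an interpretation, flagged as such); Shapes 2
corner perimeters use turning-angle corner detection on the resampled
path; loops are found as self-intersections of the pen-down path within
each stroke, tightest crossings first, orientation from the apex
relative to the crossing point.

Completion-at-first-lift is measured as the maximum arc-length progress
of the first stroke's nearest-point projection onto the template path,
in percent. Nearest-template assignment ties always go to the
lower-indexed template element.

## Age normalization

Handwriting skill improves sharply between 7 and 11 years, so raw
features confound age with impairment. Each feature of each tested child
is standardized against reference subjects at most 183 days younger or
older (our fixed reading of "6 months"), with the sample (n − 1)
standard deviation. Windows with fewer than 2 reference subjects widen
symmetrically to the smallest window holding 2 (with a warning); zero
spread yields z = 0. Failed extractions are imputed as z = 0 — the
reference mean — after standardization.

Crucially, the reference cohort is disjoint from the classified cohort
(enforced by subject id), so standardization parameters never depend on
the train/test split: the transformation cannot leak test information.
Two limitations are worth knowing. Near the edges of the reference age
range the window is necessarily asymmetric, leaving a small systematic
bias against a within-window age trend; and with finite cohorts the
correlation between z-scored features and age retains pure sampling
noise of order 1/√n. The decorrelation test therefore uses interior ages
and cohorts large enough for the bound it asserts.

## Evaluation pipeline

Classification runs a four-step pipeline fitted strictly on training
rows: (1) greedy correlation filtering in canonical registry order — a
feature is dropped when its absolute Pearson correlation with an
earlier kept feature exceeds 0.85 (constant features are kept, their
correlation treated as 0, with a warning); (2) standardization to
training mean and sd; (3) embedded selection of 10 features by absolute
linear-SVM coefficients (C = 0.1) or impurity importance of 100
extremely randomized trees, ties broken by canonical order; (4) one of
nine classifiers: random forest (500 trees), extremely randomized trees
(500), a single-hidden-layer perceptron (12 logistic units, up to 1000
epochs), four SVM kernels, Gaussian naive Bayes, and discrete AdaBoost
(SAMME) over depth-1 decision stumps, which is implemented in-package.
Remaining hyperparameters are fixed library defaults recorded in
`pipeline_config()`.

Evaluation is stratified 5-fold cross-validation repeated 100 times
(folds are stratified so each fold preserves the group balance; the
repeat index seeds the fold shuffler and every stochastic fit of that
repeat, making the whole report reproducible from the configuration
alone). Metrics pool each repeat's five fold confusions — every subject
is predicted exactly once per repeat — and are summarized as mean ± sd
over repeats; sensitivity is the detection rate on the DYS class.
Feature stability is reported as the fraction of the 500 train/test
splits selecting each feature, with a report of features above 40%.

Cohort construction utilities mirror the matched-pairs design: for each
DYS child, `pair_match()` picks the unused same-gender, same-laterality
TD candidate with the smallest absolute age gap (ties to the younger),
processing DYS subjects in ascending age order.

## The synthetic cohort

`simulate_drawing()` traces a template at constant speed (default
40 mm/s) at 200 Hz and then degrades it through interpretable channels:
band-limited Gaussian tremor (4–12 Hz, added orthogonally to the path —
inside the preprocessing passband by design, so it survives filtering),
random mid-stroke freezes, random pen lifts that occasionally resume a
few millimetres behind the lift point (backtracking), per-loop size
variability, and pen-up transitions between template components. Skill
scales with age: noise amplitudes are multiplied by
`1 + 0.15 · (11 − age in years)`, so the moving Z-score has a real age
bias to remove. A DYS profile multiplies the noise channels (defaults:
tremor ×2.5, lifts ×3, stops ×3, backtracking ×2, variability ×2).
These multipliers are calibration knobs for testing the pipeline, not
estimates of real effect sizes, which are unknown to us; with all
channels at zero the trace is template-exact and every MSE-type feature
is 0, loop counts are 6/6, the oval direction count is 4 and the circle
diameter ratio is 1.

`simulate_feature_table()` complements the drawing simulator at the
feature-table level: standard-normal noise over the full registry with a
configurable standardized effect `d` injected into a known subset of
features for the DYS group. The recovery experiments use d = 1.2 in 10
features on a 43 + 43 cohort; the permutation-null experiment permutes
labels on 200 subjects and checks that repeated-CV accuracy stays within
[0.45, 0.55] over 20 repeats (scaled down from 100 to keep the default
suite quick — problem sizes in the tests are chosen so each suite file
runs in seconds to a few minutes).

What passing these tests shows — and what it does not: the synthetic
writer produces clean template traversals with stationary noise; real
children reorder sub-movements, vary speed strategically, and produce
effects correlated across features in ways no multiplier reproduces.
Synthetic results validate the machinery (formulas, leakage safety,
selection behaviour), not clinical performance; headline accuracies
reported on private clinical cohorts are not reproducible here and the
package makes no attempt to imitate them.

## Numerical choices and degenerate inputs

* Tie-breaks are deterministic everywhere: canonical registry order for
  features, lower index for template assignment, younger candidate in
  pair matching, higher peak first under the separation rule.
* Zero-displacement trajectories get uniform step distributions;
  all-zero series have undefined SNR (an error), empty drawings are
  errors at segmentation but findings (not exceptions) in
  `validate_recording()`.
* Strokes shorter than 4 samples contribute nothing to kinematic
  aggregates; corners with too little flanking path are skipped in turn
  quality; lines never touched yield `NA` for that line's features, and
  table-level imputation maps `NA` to z = 0.
* The loop detector ignores crossings spanning fewer than 5 samples or
  bounding boxes under 1 mm (pen-tremor artifacts), and resolves nested
  or overlapping crossings tightest-first.

## Known limitations

The stimulus templates are package constants, not the original printed
sheets; absolute MSE values are therefore comparable within this
package, not across instruments. The z-score edge bias noted above is
inherent to one-sided age windows. AdaBoost is a from-scratch SAMME
implementation with stumps; it matches the standard algorithm but not
any particular library's refinements. The CLI (`inst/cli/grapho`) is a
thin wrapper over the exported functions and assumes the directory
layout produced by its own `simulate` subcommand.
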