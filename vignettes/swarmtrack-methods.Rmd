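---
title: "Classifying swarming flight tracks by one-class segment voting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying swarming flight tracks by one-class segment voting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmtrack)
```

## The problem

Male mosquitoes of swarming species aggregate above a landmark at dusk and
fly in sustained, quasi-circular orbits while waiting for females. A female
entering the swarm couples with a male quickly; the pair, tracked as a
single entity, flies briefly and erratically before leaving. Tracks of the
different classes therefore differ grossly in *duration* — males can be
tracked for minutes, couples for seconds — but that difference is partly an
artefact of the recording (a fixed, finite field of view) and of the mating
biology itself, not of flight style. `swarmtrack` implements a pipeline
that deliberately removes the duration signal: every track is cut into
equal-duration segments, each segment is classified on its flight
characteristics alone, and the segment calls are voted back into a
track-level decision.

Because females and couples are rare and heterogeneous while males are
abundant and homogeneous, the classifier is *one-class*: a nu-parameterised
one-class SVM learns a boundary around male segments only, and anything
outside is an anomaly (non-male). The open-world design means novel classes
(other species, unknown labels) are handled without retraining.

## Pipeline stages and their parameters

1. **Quality control** (`detect_outlier_trials`). Recording sessions
   ("trials") can be corrupted by weather; wind drags the whole swarm and
   inflates velocities. Each trial's mean (duration, distance-travelled)
   centroid is scored against the normal-theory 95% ellipse
   (chi-squared Mahalanobis bound, 2 df) fitted to the *other* trials'
   track-level points. The leave-one-trial-out fit matters: with a handful
   of trials, a grossly anomalous trial inflates a pooled covariance enough
   to mask itself. Flags are advisory; exclusion is a configuration choice.
2. **Track filtering** (`filter_short_tracks`). Tracks shorter than two
   windows are dropped so every voted track rests on at least two segments.
   Duration is `t_N - t_0` in seconds, not a sample count, because windows
   are specified in seconds.
3. **Segmentation** (`window_track`). Window 1.6 s, overlap 0.8 s by
   default — the grid-search optimum for the field data this design
   targets. Windows anchor at the first timestamp and advance by
   `window - overlap`; a segment takes every sample within the closed
   window, so at exactly 25 Hz a 1.6 s window holds 41 samples (40
   intervals). Trailing partial windows are discarded: all segments must be
   equally sized in duration. With zero overlap adjacent segments share at
   most the single boundary sample.
4. **Feature extraction** (`extract_features`): 237 features per segment,
   described below.
5. **Selection** (`select_features`): two-sided Mann-Whitney U per feature
   (male vs non-male segments), Bonferroni threshold `0.01 / n` over the
   `n = 237` candidates, then correlation pruning: transitive-closure
   groups at |Pearson r| >= 0.85 keep one representative each — the member
   with the smallest screening p-value, ties broken by schema order.
   Transitive closure (rather than greedy sequential grouping) makes the
   result order-independent. If no feature passes the screen (a null
   dataset), the screen is advisory and the full candidate set is pruned,
   so a detector can still be fitted.
6. **Detection** (`fit_detector`, `predict_segments`, `vote_tracks`).
   Z-score standardisation is fitted on male training segments only and
   applied unchanged to test data. The one-class SVM (radial basis kernel,
   nu = 0.20 by default; bandwidth `1/(n_features x mean variance)` of the
   standardised training data) yields a signed distance to the hyperplane;
   the logistic function maps it to a pseudo-probability. Tracks are called
   by the mode of their segment calls; an exact tie is anomalous
   (non-male) — the conservative choice for a detector whose purpose is to
   notice non-males. The track-level ranking score is the mean segment
   decision value, chosen over the vote fraction for smoothness (it breaks
   far fewer ties in ROC/PR curves); it is a package design choice, not
   part of the voting rule.
7. **Evaluation** (`make_folds`, `run_fold`, `compute_metrics`). One fold
   per unordered pair of male trials: those two trials are the male test
   set, the remaining male trials train the scaler and SVM. Couples,
   females and focal males outside the validation trials are test-only.
   Expected calls: male and focal-male tracks are male; couple and female
   tracks are non-male. Metrics (accuracy, balanced accuracy, precision,
   recall, F1, ROC AUC, PR AUC, per-subclass accuracy) are computed per
   fold at track level, averaged across folds, with percentile-bootstrap
   95% intervals over fold scores (the bootstrap is internally seeded, so
   reports are reproducible); confusion counts are pooled by summation.
8. **Tuning** (`grid_search`): exhaustive, deterministic search over
   nu (0-1 by 0.01), the four kernels, window 1-10 s and overlap 0.2-5 s
   (0.2 s steps), maximising balanced accuracy on a held-out validation
   trial set; infeasible combinations (overlap >= window, nu = 0) are
   skipped with a logged count. Re-segmentation happens inside the loop,
   since window and overlap change the segments; extraction and selection
   are cached per (window, overlap) because nu and the kernel cannot affect
   them. Ties prefer smaller nu, then smaller windows (simpler boundary,
   finer temporal resolution).
9. **Attribution** (`attribute`): permutation-sampling Shapley values.
   Each Monte-Carlo draw samples a feature ordering and a background row;
   walking the ordering, the marginal change in the decision value from
   switching a feature to the explained row's value is credited to that
   feature. The per-draw credits telescope to `f(x) - f(background)`, so
   local accuracy (baseline + attributions = decision value) holds exactly
   at any sample count; symmetry and the dummy axiom hold in expectation
   and are tested at sampling tolerance. Attributions explain the signed
   decision value: positive contributions push towards the male class.

### Where selection gets its non-males

The detector trains on males only, but the Mann-Whitney screen needs both
classes. All non-male trials would naturally sit in the test set, and
screening on test rows would leak information. The package therefore
screens each fold's training males against the non-male segments of the
designated *validation* trials — the same trials used for hyperparameter
tuning, which are excluded from every fold's test set. The leakage test in
the suite perturbs test rows and asserts bit-identical selection, scaler
and SVM.

## The feature battery

Every segment yields 25 per-timestep series and 12 whole-segment scalars.
Series are reduced by a nine-statistic summary: mean, median, standard
deviation (n-1), 1st and 3rd quartile (linear interpolation), moment
skewness and excess kurtosis (zero for constant series, where they are
undefined), the number of local extrema (strict sign changes of the first
difference) and the number of zero crossings (strict sign changes, exact
zeros skipped). Strictness is a deliberate choice: plateaus and exact zeros
do not invent events.

* **Kinematics** (12 series): axial velocity, acceleration and jerk per
  axis from second-order central finite differences (one-sided second-order
  stencils at the boundaries; exact for quadratic motion), the unsigned 3D
  speed, and the signed radial acceleration `d|v|/dt` and radial jerk.
  Signed raw 3D velocity is deliberately absent — the insect only flies
  forward, so speed carries the magnitude information.
* **Angle of flight** (1 series): turning angle between consecutive
  displacement vectors, in [0, pi], arccos argument clamped to [-1, 1].
* **Angular velocity and acceleration** (8 series): the turning angle per
  unit time and its forward difference, for the XY, YZ and XZ projections
  and the full 3D path.
* **Orthogonal velocity components** (3 series): persistence, turning and
  inclination velocities from spherical-coordinate angle increments; the
  azimuth uses `atan2` (the printed ratio form loses the quadrant). The
  identity P^2 + T^2 + I^2 = v^2 holds to machine precision and is tested
  on a thousand random segments.
* **Centroid distance** (1 series): distance of each sample to the segment
  centroid — flat for smooth circular motion.
* **Straightness**: path length over start-end chord, >= 1, exactly 1 for
  collinear monotone motion.
* **Convex hull volume and surface area**: computed by an incremental 3D
  hull written for this package (no installed R package provides 3D hull
  metrics); coplanar segments get volume 0 and area equal to both faces of
  the flat hull; verified against the cube, the regular tetrahedron and
  interior-point invariance.
* **Planar curvature** (6 scalars): signed curvature of the three
  projections from forward-difference derivatives, summarised by mean and
  SD per plane.
* **Curvature scale space** (2 scalars): each projection re-parameterised
  to normalised arc length (64 bins), convolved with Gaussian kernels over
  a 16-point log-spaced sigma grid from 0.5 to 8 samples; curvature
  zero-crossing locations per scale form the CSS image, reduced per
  arc-length bin to the maximum sigma with a crossing; the feature is the
  mean and SD of that signal averaged over planes. The sigma ceiling of 8
  keeps the largest kernel below half the resampled curve; the grid is
  configurable. Inflection locations are invariant to translation, rotation
  and uniform scaling.
* **Fractal dimension**: `log(path length) / log(bounding-box diagonal)` —
  1 for straight paths, approaching 2 for plane-filling motion. The
  formula is kept exactly in its path-length/scaling-factor form, with two
  documented consequences: it inherits the metre unit (a diagonal of
  exactly 1 m is a sentinel-handled singularity), and the axis-aligned
  bounding box makes it the one feature that is *not* invariant to rigid
  rotation.

**Degenerate-step policy.** Stationary frames define no direction; such
steps are dropped from angle-based series rather than imputed with
fabricated angles. A series with fewer than three valid values, a
zero-length chord, or a coincident point cloud yields an `NA` sentinel,
resolved by column-median imputation when the feature matrix is assembled.

## The synthetic swarm generator

`simulate_swarm` emulates the *structure* of field recordings so the whole
pipeline is testable without access to restricted data: 8 male trials of
12 long tracks (15-40 s) and 4 couple trials of 30 short tracks (4-10 s),
plus 5 female and 6 focal-male tracks hosted in the couple trials — at the
default windowing roughly 3000 male and 1000 non-male segments, mirroring
the class imbalance such field datasets show. Males fly noisy circular
orbits (radius 0.3-0.6 m, angular rate 1.5-3 rad/s, slowly wandering
radius and height, ~2 mm measurement noise, small vertical variance) above
a fixed point at 25 Hz. Non-males follow the same orbital baseline plus an
Ornstein-Uhlenbeck-style correlated acceleration process with heavy-tailed
(t, 3 df) innovations and occasional large kicks — erratic, high-
acceleration flight. The `erraticity` scale interpolates between the two
regimes: at 0 the classes are statistically identical and the pipeline's
balanced accuracy collapses towards 0.5, which is exactly what the
label-shuffled control in the acceptance suite verifies.

What the generator does *not* emulate: aerodynamics, swarm interactions,
stereo-reconstruction depth error, or the between-trial heterogeneity
(different chromosomal forms, swarm markers, weather) that makes real field
data hard. Passing the parameter-recovery check (fold-averaged track-level
balanced accuracy >= 0.9 on the default dataset) therefore demonstrates
that the pipeline's plumbing — segmentation, features, selection,
standardisation, voting, cross-validation — recovers a class signal it is
entitled to recover; it does not predict field performance, where the
behavioural contrast is far subtler.

## Numerical choices and degenerate inputs

* Mann-Whitney U uses the normal approximation with tie and continuity
  correction (segment counts are in the thousands); it matches
  `wilcox.test(exact = FALSE)` to 1e-12 in the suite and constant features
  get p = 1, never a selection.
* Windows tolerate a relative 1e-9 slack at their closing boundary so that
  floating-point representations of step multiples do not drop a final
  sample or a final window.
* A constant feature in male training data would make the Z-score divide
  by zero; its SD is treated as 1 (centring only).
* e1071's one-class decision values scale with the dual normalisation (a
  duplicated training set doubles them); calls and rankings are invariant,
  which is what the suite asserts.
* The random-walk fractal-dimension check is the one deliberately red test
  in the suite: the estimator's bounding-box diagonal grows as about
  1.76 sqrt(N), so its expectation at N = 1e5 steps is about 1.84,
  approaching the Brownian ideal of 2 only as N grows without bound. The
  suite keeps the +-0.15 band around 2 and documents the measured 1.836
  rather than widening the band to fit the estimator.

## Problem sizes used by the suite

Unit and property tests run on purpose-built small fixtures (tens of
segments). The acceptance checks run the generator at its default size
(~4000 segments, 28 folds, plus a label-shuffled control on the same
feature matrix); the full run completes in a few minutes on a single core.
The tuning grid is searched exhaustively over whatever grid it is given;
the suite demonstrates correctness on restricted grids and checks the full
default grid's feasibility count by enumeration, since a full end-to-end
sweep (~430,000 configurations, each with re-segmentation and
re-extraction) is not a sensible desk-scale computation.

## Known limitations

* Feature extraction is plain R; ~25 ms per segment. Fine for 1e4
  segments, not for 1e7.
* The CSS sigma grid and 64-bin arc-length resolution are sensible
  defaults, not tuned values; very short segments (< 8 samples) skip CSS.
* Tracks are assumed gap-free; there is no gap-aware windowing.
* The fractal dimension keeps its printed unit dependence; comparing its
  values across datasets recorded in different units would be meaningless.
* The whole-track duration/distance baseline classifier that outperforms
  segment features on duration-confounded data is intentionally out of
  scope: removing the duration confound is the point of the design.
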