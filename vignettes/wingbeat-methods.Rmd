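---
title: "Methods: wingbeat-resolved kinematic and neural population analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wingbeat-resolved kinematic and neural population analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingbeat)
```

## The analysis problem

Flight in bats (and comparable behaviors in other flying animals) unfolds
on two nested timescales: a fast, quasi-periodic wingbeat cycle near 8 Hz
(~125 ms per cycle) and slow, multi-second flight paths assembled from
dozens of such cycles at speeds of roughly 4-5 m/s. A session pairs
synchronized behavioral streams — 3D body trajectory at ~120 Hz, 20 pose
keypoints, a 3-axis accelerometer — with spike times from up to hundreds
of simultaneously recorded motor cortical units. The package asks, stage
by stage: how reproducible are flights of the same path; how precisely is
each individual wingbeat controlled; which units are recruited on which
wingbeats, at which wingbeat phase, and driven by which kinematic
features; and how many dimensions the resulting population activity
occupies.

Every stage is validated against a synthetic session generator that
plants the quantities the analyses are supposed to recover. Because the
generator is part of the package, each estimator has a known ground truth
to be scored against, and all acceptance-style checks are property-based
(type-I error control, recovery of planted parameters) rather than
comparisons to any particular recorded dataset.

## The synthetic session generator

`simulate_session()` draws everything from one seed, so a configuration
reproduces bit-identical sessions. Its defaults are the study conditions
used throughout the tests; they were fixed once, from the flight regime
the analyses target, and are not tuned per test.

* **Trajectories.** Flights are smooth closed loops from a perch
  (elliptical, flown in either direction, or climb/descend variants that
  share an identical prefix before diverging — the divergence point is
  recorded, which gives the cross-path divergence analysis a planted
  onset). Cruise speed 4.5 m/s with 0.3 s cosine speed ramps at takeoff
  and landing; flights are separated by 2 s perch rests so segmentation
  is unambiguous. A smooth per-flight perturbation (three sine harmonics,
  sd 0.05 m) creates flight-to-flight variability.
* **Wingbeats.** The phase advances at 8 Hz with i.i.d. Gaussian
  per-cycle period jitter (sd 3 ms, truncated at three sd, matching a
  narrow period distribution around 125 ms).
* **Stroke envelopes.** Each wing's stroke amplitude couples to the
  normalized yaw rate with opposite signs (`1 ± gain·yaw`,
  gain 0.6), so turns produce left-right asymmetries of the planted
  sign. On top of that, an AR(1) process across cycles (sd 0.08,
  correlation 0.6, independent per wing and per proximal/distal keypoint
  group) models the cycle-by-cycle stroke adjustments a real animal
  makes. This term matters twice: it sets the planted decay timescale of
  the adaptation-vector similarity curve, and it breaks the otherwise
  perfect collinearity between envelope features and angular velocity —
  without it the 17-feature encoding design would be rank-deficient and
  planted-weight recovery ill-posed.
* **Keypoints and accelerometer.** Twenty body-frame keypoints (six on
  the body, seven per wing) oscillate dorsoventrally as
  `amplitude · envelope · sin(theta)` and are re-projected into the
  world frame through the velocity-derived body axes; the dorsoventral
  accelerometer is `1 + 0.8·sin(theta)` in g plus white noise
  (sd 0.05 g).
* **Units.** Four response classes: tonic phase-locked units whose rate
  follows `exp(kappa·cos(theta − phi))`, normalized so their phase
  distribution is exactly von Mises (population resultant vector length
  `I1(kappa)/I0(kappa)` — the Bessel-ratio oracle used in recovery
  tests); kinematically tuned units whose per-cycle log rate is a linear
  function of the z-scored cycle features; group-selective units that
  fire one precisely timed spike (millisecond-scale Gaussian jitter) at
  a fixed phase only in their active wingbeat groups; and unmodulated
  Poisson units. An optional low-rank latent drive (GP factors per
  flight) adds shared variability.
* **Latent-factor populations.** `simulate_factor_trials()` generates
  spike-count trials whose rate is `(d + Cx)^2` with GP latents `x`, so
  the square-root counts — the observation scale of factor analysis —
  are linear in the planted factors. The session generator's log-link
  latent drive is deliberately *not* used for factor-count recovery: the
  exponential creates interaction terms of higher linear rank, so it is
  not a k-factor population in the factor-analysis sense.

What the generator does **not** emulate: aerodynamics, pose-estimation
artifacts (occlusion, identity swaps), electrode drift, spike-sorting
errors, or cross-class mixtures within one unit. Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
structure, not robustness to every failure mode of real recordings.

## Kinematics and wingbeat processing

**Smoothing and derivatives.** Positions are smoothed with a zero-phase
Gaussian (sd 25 ms) before central differencing — small enough to
preserve 8 Hz content (sd is a fifth of the cycle), large enough to
suppress sample noise in accelerations. Speed is `|v|`, g-force
`|a|/9.81`, angular velocity the rotation rate of the velocity direction
`|v × a|/|v|²`, flight-path angle `asin(vz/|v|)`. On analytic circles
and helices these match closed forms to better than 1% away from the
smoothing edges.

**Flight segmentation** thresholds smoothed speed at 1 m/s for at least
1 s and pads each epoch outward along the decreasing speed ramp, stopping
at a small floor (2% of threshold) so that smoothing leakage into the
rests does not drag boundaries outward.

**Path clustering** is average-linkage agglomerative clustering on the
RMS distance between trajectories resampled to 200 points, cut at 0.3 m.
The metric is deliberately direction-sensitive (no temporal-orientation
merging): the same loop flown in opposite directions is two different
behaviors for the motor system and is kept as two paths. The 0.3 m cut
sits an order of magnitude above the within-path perturbation distance
(~0.05-0.1 m) and below the separation of the most similar built-in
template pair (~0.45 m).

**Wingbeat detection** band-passes the dorsoventral accelerometer
(4-14 Hz Butterworth, zero-phase), takes the analytic-signal phase, and
places cycle boundaries at phase-zero crossings with sub-sample
interpolation of the unwrapped phase. The phase origin is the upward
zero-crossing of the oscillation; this convention is arbitrary but
consistent across generator and detector, and all circular statistics are
invariant to it. Two gates reject non-oscillatory input: a flight whose
in-band variance fraction is below 0.5 yields no cycles, and cycles whose
analytic amplitude falls below 20% of the flight median are discarded
(landing artifacts).

**Reproducibility** correlates each flight's resampled feature trace with
the leave-one-out mean of the other flights of the path. Leave-one-out
(rather than all-pairs or correlation with the grand mean) avoids
inflating the score by including the flight in its own reference.

**Wingbeat grouping** clusters the cycles of one path over
`[adaptation vector; per-cycle kinematics; ordinal position]` with
k-means, k = median cycles per flight, centers initialized at per-ordinal
means, and labels re-ordered by mean ordinal. Two numerical choices
matter. The kinematic block is rescaled to ~unit total variance so its
influence does not grow with the number of columns, and the normalized
ordinal enters with weight 12. The weight was set so that the noiseless
generator reproduces exact ordinal grouping (any weight does) *and* the
grouping stays ordinal-dominated under default noise — mirroring the
empirical observation that kinematically similar cycles across flights
are essentially the i-th cycle of each flight. With a weak ordinal term
the clusters remain temporally ordered but their boundaries wander by
±1 cycle, which is a different (and defensible) grouping; we prefer the
ordinal-stable one because group labels feed trial-averaging downstream.

## Unit statistics

**Flight modulation** is tested by the circular-shift permutation test:
the statistic is the mean pairwise Pearson correlation of per-flight
smoothed rate traces (10 ms bins, 25 ms Gaussian, traces resampled to a
common length); the null circularly shifts each flight's spike train by
an independent uniform offset of at least one wingbeat period (shifts
near zero would reproduce the observed statistic and sap power). P-values
use the `(1 + #null ≥ obs)/(1 + N)` convention, so `p ≥ 1/(1+N)` always;
decisions are Benjamini-Hochberg at q = 0.01 across units.

**Phase locking** uses the resultant vector length (RVL) of spike phases.
The null rotates each flight's phases by one independent uniform offset —
preserving within-flight spike patterns and testing only the consistency
of phase across flights — with BH at q = 0.05 within each path. Units
with fewer than 20 spikes on a path are excluded rather than tested at
hopeless power.

**Cross-path phase decoding** regresses `[sin θ, cos θ]` on binned
population rates of continuously active phase-locked units, trains on one
path and tests on another. The reported score is the test R² (joint over
the sine and cosine targets) divided by the cross-validated within-train
R² — "how well does phase generalize across paths, relative to how well
it can be decoded at all". The normalization makes scores comparable
across populations of different intrinsic decodability; a denominator
R² ≤ 0 marks the score undefined.

## Recruitment decoding

Barcodes binarize per-cycle spike counts (unit active vs silent per
wingbeat). Wingbeat-group decoding uses one-vs-rest linear SVMs (cost 1,
class-balanced weights — the binary sparse features and modest class
sizes argue for the simplest large-margin classifier), stratified 5-fold
cross-validation, a full confusion matrix, band accuracies (fraction of
predictions within ±b groups), and a label-shuffle null that re-runs the
entire pipeline per permutation. The similarity-lag curve computes cosine
similarity between per-cycle population vectors (counts by default,
binary optionally) at increasing wingbeat lags within each flight; an
exponential fit to this curve gives a decay constant directly comparable
to the kinematic adaptation-vector curve, testing whether neural
recruitment changes on the timescale at which stroke kinematics change.

Cross-path divergence z-scores per-unit mean rate traces with pooled
mean/sd across both paths, averages `|z_A − z_B|` over units in 250 ms
windows stepped by 5 ms, and compares against the odd-vs-even
within-path control computed identically.

## Encoding models

Each unit's per-cycle spike count is modeled as Poisson with log rate
linear in 17 z-scored cycle features (speed, g-force, angular velocity,
flight-path angle, velocity and acceleration components, curvature,
wrist/wingtip upper envelopes left and right, wrist asymmetry, period —
the registry is configurable since the exact feature inventory is a
modeling choice). Feature selection is a Poisson elastic net (mixing 0.5
— between ridge's grouping of correlated features and lasso's sparsity)
with the penalty chosen by 5-fold cross-validated deviance under the
one-standard-error rule; the selected set is refit without penalty, and
`cv pseudo-R² = 1 − CV deviance(model)/CV deviance(intercept-only)`
pooled over folds. A deviance-based pseudo-R² is the standard currency
for cross-validated Poisson fits. Non-convergent refits (separation on
sparse units) fall back to a lightly ridge-penalized IRLS solver with a
warning. The participation ratio of the squared selected weights,
normalized by the number of selected features, summarizes how distributed
each unit's tuning is (1 = maximally mixed selectivity).

## Population dimensionality

**Group-mean matrices** warp each cycle to 15 equal time bins, average
within wingbeat group, and concatenate groups into a units × (groups ×
bins) matrix; units below a split-half (odd/even cycles) reliability of
0.3 are removed so noise units do not masquerade as dimensions.

**PCA** reports the eigenvalue spectrum, `n90` (components to 90%
explained variance) and `n90` as a fraction of units, plus
participation ratios of the "core" subspace (PCs up to 50% cumulative
variance) and the "extended" subspace (the rest), each normalized by its
size — an extended-subspace PR well below 1 indicates a structured,
non-isotropic tail.

**Demixed PCA** splits the trial-averaged tensor into a time-only
marginalization (mean across groups) and the group-specific remainder
(group and group × time combined); the two are orthogonal and sum to the
centered tensor exactly. Each marginalization is compressed by
reduced-rank ridge regression of the marginalized data on the full data
(10 components per marginalization), with the ridge penalty chosen by
cross-validation on odd/even split-half trial averages; explained
variance per marginalization is measured against total centered variance,
and the headline statistic is the group-specific to group-invariant EV
ratio. With a single trial per condition an analytic heuristic penalty is
used and flagged.

**GPFA** fits, by EM, a factor-analysis observation model
(`y = Cx + d`, diagonal noise) with an independent unit-variance
squared-exponential GP prior per factor and per-factor timescales
optimized in each M-step (1-D search on log timescale) — the per-factor
timescales let slow path-level and fast wingbeat-level factors coexist.
Counts are square-root transformed by default. Kernels carry a small
noise floor (1e-3) and jitter (1e-6) for conditioning; the posterior over
all latents is computed jointly per trial (the same posterior covariance
is shared by trials of equal length, which makes the E-step cheap).

**Dimensionality selection** uses leave-one-neuron-out prediction: for
each candidate factor count, latents are inferred without the held-out
unit and its activity predicted from them; the selected range is all
counts within 1% of the minimum error. Two implementation details proved
essential. First, the error must be evaluated on held-out *trials*
(2-fold trial CV): evaluated on training trials, the loadings of the
held-out unit absorb its noise and the error decreases monotonically with
dimensionality, so the 1% rule never brackets the true count. Second,
recovery simulations must plant factors on the observation scale the
model assumes (see `simulate_factor_trials()` above).

## Problem sizes and numerical choices

The validation suite runs on deliberately small instances: standard
sessions of 2 paths × 6 flights (~300 wingbeats, 24 units), encoding
sessions of ~500 cycles, GPFA populations of 15 units × 40 bins × 12
trials with factor grids up to 5. These sizes were chosen as the smallest
at which the planted effects are estimable with comfortable margins, and
they keep the whole suite reproducible on a laptop. Permutation tests use
200 shuffles in validation (the BH thresholds probed there do not require
finer p-resolution); the package defaults to 500.

Degenerate inputs are handled explicitly rather than by accident: silent
units get `p = 1` in the modulation test and are excluded from phase
testing; constant traces are excluded from reproducibility with a count;
zero vectors are dropped from similarity curves; undersized wingbeat
groups merge into their ordinal neighbor before decoding; rank-deficient
matrices pad their spectrum with zeros; empty extended subspaces and
undefined normalized scores are flagged, not silently zeroed.

## Known limitations

* The wingbeat-group k-means is ordinal-dominated by design; sessions in
  which kinematically equivalent cycles occur at *different* ordinal
  positions (e.g. variable-length flights of the same path) would need a
  smaller ordinal weight and a warped ordinal coordinate.
* The dPCA implementation reports the combined group + group × time
  marginalization rather than separating the two; the ratio statistic is
  unaffected.
* GPFA assumes equal-length trials; flights are truncated to the
  shortest when the pipeline builds trials.
* The phase decoder's normalization divides two R² estimates; with few
  flights the denominator is noisy and scores can exceed 1.
* Spike generation uses a 1 ms discretization of the inhomogeneous
  Poisson process; phase-locking structure sharper than ~1 ms cannot be
  planted.
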