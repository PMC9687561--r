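---
title: "Quantitative MRI profiling of the hippocampal septotemporal axis: models and methods"
author: "hippoaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI profiling of the hippocampal septotemporal axis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

After a lateral fluid-percussion injury — a standard rat model of traumatic
brain injury — the hippocampus develops a cascade of pathologies (edema,
cell loss, gliosis, axonal sprouting) whose severity varies along the long,
curved septotemporal axis of the structure. The question this package
addresses is whether early quantitative MRI of the hippocampus (T2, T2*,
and diffusion-tensor scalars imaged on days 2, 7 and 21 after injury) can
prognosticate two later outcomes: post-traumatic epilepsy, diagnosed months
later by video-EEG, and cognitive impairment, diagnosed by water-maze
performance.

`hippoaxis` implements the full analysis as a reusable pipeline:

1. **Relaxometry** — per-voxel monoexponential fits of multi-echo series
   yield T2 and T2* maps.
2. **Diffusion scalars** — per-voxel single-tensor log-linear fits yield
   eigenvalues, FA, MD, RD and the Westin shape measures.
3. **Axis profiling** — each hippocampus mask is skeletonized into a
   parameterized midline; every voxel is projected to an arc-length
   position (0 mm = temporal end) and each map is summarized as a
   Gaussian-weighted mean and SD at positions along the axis.
4. **Position-wise statistics** — Mann–Whitney U tests per
   (parameter, day, statistic, side, position) cell with Benjamini–Hochberg
   false-discovery-rate control.
5. **Prognostic models** — elastic-net logistic regression on all 48
   profile features at one position, evaluated by nested leave-one-out
   cross-validation with pooled AUC and BCa bootstrap confidence intervals.

Because the animal data of the motivating study are not publicly deposited,
the package ships a first-class **synthetic cohort generator** that
reproduces the statistical structure the analysis assumes, so every stage
is testable end to end.

## The synthetic cohort generator

### Geometry

Each hippocampus is modelled as a C-shaped circular arc (default length
12 mm, opening angle 1.75 rad) with a tapering tube radius (1.5 mm at
mid-axis falling to 1.1 mm at the poles), tilted slightly out of the axial
plane so the curve is genuinely three-dimensional, and rasterized on an
anisotropic voxel grid (default 0.20 mm in-plane, 0.50 mm slices —
the acquisition class of high-field rodent imaging). The rodent literature
gives the dorsoventral extent of the rat hippocampus as roughly 10–12 mm;
12 mm is our documented default. The analytic centerline is retained with
every mask, giving downstream code an exact arc-length oracle.

Per-animal geometric jitter (translation SD 0.15 mm) is applied by default;
setting `geometry_jitter = 0` makes all animals share one geometry, which
the calibration simulations use so that skeletons need to be computed only
once per side.

### Signal structure

Quantitative maps are generated directly at the parameter level:

> value = baseline + sum of applicable effect amplitudes (windowed in arc
> length with 0.5-mm half-cosine edge ramps) + per-animal offset + voxel
> noise.

Baselines are deliberately round, rodent-plausible numbers (T2 = 55 ms,
T2\* = 40 ms, MD = 0.7e-3 mm^2/s, FA = 0.25, ...); they are generator
knobs, **not** measured values. Three variance components are exposed:

* `noise_sd` — voxel-level map noise (e.g. 2 ms for T2);
* `animal_sd` — a per-animal offset per parameter, constant across the
  map (e.g. 1.5 ms for T2). This is what limits group discrimination at
  cohort level: profile averaging suppresses voxel noise almost entirely,
  so without biological between-animal variation any injected effect would
  be trivially detectable;
* `sd_scale` on an effect — multiplies voxel noise inside the effect
  window, which is what moves the *SD* profile statistic.

Raw-signal synthesis is separate: monoexponential echo decays
(`synthesize_echo_series`) and single-tensor diffusion-weighted signals at
b = 2000 s/mm^2 with 60 Fibonacci-sphere directions plus 4 b = 0 volumes
(`synthesize_dwi`). Noise is additive Gaussian by default with a Rician
switch; plain Gaussian is a good approximation at the SNR of averaged
acquisitions, and the switch documents the approximation.

### Cohort structure

Group sizes default to 16 sham + 68 TBI. Outcome labels among TBI animals
are drawn with deterministic rounding of the prevalences (22% epilepsy
giving 15 animals, 81% cognitive impairment giving 55), with the seeded
assignment deciding *which* animals. The default injected effects emulate
the qualitative injury pattern: an early global ipsilateral T2/T2*
increase that reverses septally by day 7–21, a transient day-7 MD
increase, septal FA loss with a linear-to-planar shift of tensor shape,
milder septal contralateral changes, a moderate contralateral mid-axis
(3–6 mm) signature attached to the cognitive-impairment label — and **no
effect at all attached to epilepsy**, so that contrast is a designed null.
Amplitudes are chosen relative to `animal_sd` (large for injury, moderate
for cognition), once, as plausibility choices. TBI animals additionally
receive progressive ipsilateral mask shrinkage (radius scale 0.97/0.93/0.88
on D2/D7/D21) so the volume models have signal.

What the generator does **not** emulate: k-space artefacts, partial-volume
mixtures at tissue boundaries, registration error between animals,
spatially correlated noise, or subfield anatomy. Passing tests therefore
validate the estimators and the statistical machinery, not robustness to
those real-data complications.

## Relaxometry

The decay model is `S(TE) = S0 exp(-TE/T)` with `S0 > 0` and
`T ∈ (0, t_max]`, fitted by nonlinear least squares per voxel. Because the
optimal `S0` given `T` is available in closed form, the fit reduces to a
one-dimensional minimization over the rate `1/T` (variable projection). The
implementation scans a log-spaced candidate grid seeded with the log-linear
estimate and refines by golden section, fully vectorized across voxels; a
64^3 volume fits in seconds. This construction guarantees the invariant
that the final residual never exceeds that of the log-linear initialization.

`t_max` defaults to twice the last echo time: beyond that, decay is not
identifiable from the sampled window, so slower-decaying voxels are clipped
there and flagged. Voxels with no positive signal are undefined and
flagged. Fits run on magnitude signals under a Gaussian-residual
assumption (no Rician correction).

## Diffusion scalars

Tensors are fitted by ordinary least squares of log-signals on the six
tensor design columns plus log S0 (one shared QR solve for all voxels with
fully positive signals). Nonpositive signals drop individual volumes; a
voxel is rejected when fewer than 7 usable volumes remain. Negative
eigenvalues are clamped to zero and flagged rather than rejected, keeping
noisy voxels usable for profiling. Eigenvalues come from the closed-form
trigonometric solution for symmetric 3x3 matrices, vectorized over voxels
and cross-checked against the dense solver in the tests.

The Westin shape measures use the trace-normalized convention:

* c_l = (λ1 − λ2) / (λ1 + λ2 + λ3)
* c_p = 2 (λ2 − λ3) / (λ1 + λ2 + λ3)
* c_s = 3 λ3 / (λ1 + λ2 + λ3)

The literature also contains a λ1-normalized variant; we chose the
trace-normalized one because its c_l + c_p + c_s = 1 identity makes the
implementation sharply testable. The choice rescales the c maps but does
not change any downstream pipeline logic.

## Axis skeletonization and profiling

The midline is extracted as a **distance-transform-penalized geodesic**
rather than by voxel thinning (no 3D medial-axis thinning implementation
exists in the R stack this package builds on, and a ridge geodesic directly
yields the single pruned endpoint-to-endpoint path that thinning plus
longest-path pruning would):

1. the mask becomes a 26-connected voxel graph with physical edge lengths;
2. an exact Euclidean distance to the background shell around the mask is
   computed (the shell hugs the curved boundary at sub-voxel offsets, which
   keeps the medial ridge sharp despite 0.5-mm slices);
3. the geodesic diameter endpoints are found and re-centred onto the
   distance ridge (among near-maximal candidates, the one nearest the
   candidate centroid — the maximal-distance set forms a plateau on
   anisotropic grids);
4. the path between them is traced with edge weights
   `length / (ridge distance)^2`, smoothed by a ±0.75-mm moving average;
5. each end is trimmed by 1 mm and extended to the tube cap along a total
   least-squares line through the final 2.5 mm, re-centring every step on
   the perpendicular cross-section centroid (this self-corrects tangent
   error and follows curvature; extension stops when the cross-section
   collapses at the cap).

Control points are placed every 1 mm and interpolated with a
piecewise-cubic Hermite polynomial (pchip); arc length 0 is the temporal
end, identified by a hint point when available (the generator's metadata)
or by the more ventral endpoint. Disconnected masks, non-tube-like masks
(longest path < 3 mm) and closed loops are rejected; loops are detected by
removing a mid-arc slab of voxels and re-checking endpoint connectivity.

Voxels are projected to the curve by dense sampling at 0.01-mm steps, ties
toward smaller arc length. Profiles use Gaussian weights
`w_i = exp(-(s_i - p)^2 / (2σ^2))` with `σ = FWHM/sqrt(8 ln 2)` and
FWHM 1.5 mm, truncated beyond 4σ (contribution < 3.4e-4 of peak); the
weighted SD is the normalized-weights population form, with values centred
before the E[x^2] − m^2 computation to avoid cancellation. Positions whose
total weight falls below 1e-6 are returned as NA and flagged. Evaluation
positions default to every 0.5 mm, matching the sub-millimetre granularity
at which results are reported. The one-voxel 6-connected surface erosion
(partial-volume guard) is applied before profiling by default, and a
configurable `drop_last_slices` reproduces the exclusion of low-SNR caudal
slices in real acquisitions (default 0 for synthetic data).

## Position-wise statistics

Each (side, day, parameter, statistic, position) cell is compared between
groups with the two-sided Mann–Whitney U test (exact for small untied
samples, normal approximation with tie and continuity corrections
otherwise — `stats::wilcox.test` semantics). The Benjamini–Hochberg
step-up procedure controls the FDR at q = 0.05 within one family per
(side, day, statistic) panel spanning positions x parameters — matching how
significance is marked per panel in along-axis figures — with a `global`
option correcting across everything at once. Whether days and sides should
form one family is genuinely ambiguous; both modes are provided and the
per-panel mode is the default, not presented as the only defensible choice.

Single-parameter discrimination is the empirical AUC (tie-aware
Mann–Whitney identity) with a BCa bootstrap CI.

## Prognostic models

At one axis position and side, the feature matrix has 48 columns: weighted
mean and SD of T2 and T2* at D2/D7/D21 and of the nine diffusion scalars at
D7/D21 (diffusion is not acquired at D2). The model is elastic-net
logistic regression at mixing 0.5 (equal LASSO/ridge weighting), intercept
unpenalized, observations weighted by inverse class frequency normalized to
sum to n.

Evaluation is a nested leave-one-out cross-validation: the outer loop
leaves out one animal; within each outer training set, predictors are
standardized to mean 0 / population SD 1 (zero-variance columns dropped for
that fold), a 100-value regularization path with `lambda.min.ratio = 1e-4`
is fitted, and the inner cross-validation (leave-one-out by default; a
seeded k-fold option exists) selects the strength minimizing class-weighted
binomial deviance, ties broken toward the most regularized model. The
held-out animal is scored with that model; probabilities pooled over all
outer folds give the cross-validated AUC, with a stratified BCa bootstrap
CI (10,000 resamples for reported intervals). A position is called
discriminative when the lower CI bound exceeds 0.5 — encoded exactly as
that rule, not as a p-value. Coefficient importance averages the
standardized coefficients over outer folds and reports the top-k
predictors by absolute averaged coefficient.

Standardization is per outer fold for validity (computing it once globally
leaks the held-out animal's values into its own score); the `global` mode
exists only to demonstrate that the leakage changes the result, which a
dedicated differential test asserts.

### A caution on pooled LOOCV AUC under the null

During validation we measured the null behaviour of the pooled estimator:
on pure-noise features at the study's group sizes (16/68 with class
weights, 48 predictors), the pooled leave-one-out AUC is **pessimistically
biased** — mean ≈ 0.2–0.35 rather than 0.5, in both this implementation
and an independent `cv.glmnet`-based reimplementation. The mechanism is
that the class-weighted refits differ systematically depending on which
class the held-out animal belongs to, so the pooled probabilities anti-rank
(forcing the per-fold null model restores exactly 0.5). This is a known
hazard of pooling leave-one-out probabilities rather than averaging
per-fold AUCs. Consequences: under a true null the method is conservative
(it under-reports discriminability, it does not inflate it), and the
discriminability rule (CI lower bound > 0.5) fires rarely; but a
calibration check expecting the null mean AUC to sit in a tight band
around 0.5 fails by design of the estimator. The package reports the
pooled estimator because that is the method under study; users wanting an
unbiased null should average fold-wise ranks instead.

## Numerical and runtime choices

* Monoexponential refinement: 40-point log-spaced rate grid, golden
  section to 1e-6 relative bracket width, `t_max` clipping as above.
* Gaussian profile weights truncated at 4σ; weighted SD computed on
  centred values.
* Projection sampling step 0.01 mm (tested against a 0.001-mm oracle).
* Elastic-net path: nlambda 100 down to 1e-4 of the maximal strength at
  full scale. The calibration and recovery simulations in the test suite
  run at simulation scale — inner 3-fold CV, nlambda 20 down to 1e-2,
  glmnet threshold 1e-5, a 0.35 x 0.35 x 1.0 mm grid, 100 null replicates,
  one model position per contrast — chosen once as the problem size that
  keeps the full suite practical on a single CPU while leaving every
  qualitative property intact.
* All randomness flows through explicit integer seeds; leave-one-out
  itself is deterministic.

## Known limitations

* The skeletonizer assumes a single non-branching tube-like mask; strongly
  branched or toroidal shapes are rejected rather than pruned.
* The generator's maps are drawn at the parameter level; raw-signal
  synthesis is validated by round trips but the default cohort does not
  simulate the full acquisition chain.
* Westin measures follow the trace-normalized convention (see above).
* Pooled LOOCV AUC is conservative under the null (see the caution above).
* Echo-to-echo registration, eddy-current and motion correction, template
  registration and CNN segmentation are upstream of this package's scope:
  inputs are assumed co-registered with masks supplied.
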