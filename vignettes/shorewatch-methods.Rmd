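---
title: "Shore-based cetacean habitat-use analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shore-based cetacean habitat-use analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shorewatch)
```

This vignette is the package's own account of the science it implements:
the observation model for land-based scan surveys of small cetaceans, the
covariates engineered from tides, currents and bathymetry, the kernel
density core-area analysis, and the point-process habitat model. It also
records the numerical choices and the design decisions made where the
method family leaves them open, and what the synthetic-data tests do and do
not establish about real surveys.

## The observation model

Observers on elevated coastal platforms scan a fixed sector for ten minutes
at a time, recording each sighting's bearing (built-in compass, rounded to
one degree) and its reticle reading (7x50 marine binoculars, rounded to the
nearest half reticle). Geolocation inverts that geometry:

* the platform eye height, referenced to low water, is corrected by the
  tidal height at scan time (`corrected_platform_height()`);
* the horizon of an observer at height $h$ on a sphere of effective radius
  $R_\mathrm{eff} = R/(1-k)$ sits at a dip angle $\arccos\!\big(R_\mathrm{eff}/(R_\mathrm{eff}+h)\big)$
  below the horizontal, and each reticle adds a fixed angular drop
  $\delta$; intersecting the sight line with the sphere gives the arc
  distance (`reticle_to_distance()`);
* the position is the platform displaced along the true bearing in a local
  transverse-Mercator frame (`sighting_position()`).

Three constants deserve attention. The refraction coefficient defaults to
$k = 0.13$, standard marine-survey practice; the earth radius to
6 371 000 m; and the reticle spacing to 0.00497 rad per reticle, an
instrument property of the 7x50 class that must be overridden for a
different calibration — none of these are estimable from survey data, so
they live in `geodetic_config()`. Plane trigonometry is used for the
bearing displacement: over a domain of ~20 km the grid convergence is below
0.2 degrees, far smaller than the one-degree bearing rounding.

The half-reticle rounding quantizes distance. `half_reticle_spacing_error()`
tabulates the gap between consecutive half-reticle steps: near the platform
the steps are tens of metres apart, towards the horizon they grow without
bound. This is why the detection analysis (below) caps the usable range,
and why the synthetic generator deliberately reproduces the "stepped"
appearance of real reticle data.

## Detection distance and the uniform-detection region

Habitat inference from sighting rates is only valid where detection is not
itself distance-limited. The package estimates, for each survey sector,
species and sea state, the radius at which the cumulative distance
distribution of sightings stops rising at its initial rate — the
"inflection point" — and discards everything beyond it.

`estimate_inflection()` fits a continuous two-segment least-squares line to
the empirical cumulative curve, searching breakpoints over the quantiles of
the observed distances and requiring the second slope not to exceed the
first; an improvement of less than 1% in SSE over a single line is reported
as "no decline". Two fitting domains are offered:

* `domain = "distance"` (default) fits against distance, appropriate when
  the sighting rate is roughly constant per unit distance;
* `domain = "area"` fits against squared distance; for a homogeneous point
  process over a sector the cumulative proportion is linear in the *area*
  surveyed, and the distance axis would curve quadratically even with
  perfect detection.

A known limitation, demonstrated by the closed-loop tests: when detection
*declines smoothly* past the inflection rather than dropping, the cumulative
curve's second segment is curved and the least-squares knot lands beyond
the true knee, by roughly 20% of the radius for a decline that is linear in
distance. The estimator is exact (to the candidate-grid step) when the
decline is a step to a lower constant rate; the generator's
`decline = "step"` shape exists precisely to verify that regime. Users
should regard estimated inflection radii as conservative bounds and, as in
practice, inspect the curves.

Pooling decisions (which sea states or sectors share a curve) use the
two-sample Kolmogorov–Smirnov statistic with a default threshold of 0.1 and
single-linkage grouping — a reproducible stand-in for the visual judgement
this step classically relies on; a configuration override can force any
grouping.

The filter itself (`apply_detection_filter()`) is deliberately strict:
re-sighting duplicates within a scan are removed, each species has a
sea-state cap, and every retained sighting must fall inside the inflection
radius for its (site, species, sea state). A missing radius is a
configuration error, not a silent pass.

## Environmental covariates

All surfaces live on metric rasters (ESRI ASCII interchange, 50 m cells for
bathymetry-derived layers, 300 m for current fields). From the depth grid
the package derives slope and downslope aspect by Horn's 3x3 method (the
default of the GIS tools this analysis tier uses) and the *spatial
variation* layers as the standard deviation of a cell together with its
five nearest neighbours — the rook neighbours first and then NE, a literal
reading of the conventional "5 surrounding cells"; `k_neighbors = 8` gives
the Moore neighbourhood if preferred.

Tidal current fields are stored as 25 half-hourly snapshots spanning
HW−6 h to HW+6 h, as east/north components (the "toward" convention,
clockwise from true north — stated here because conventions differ).
Sampling at an arbitrary time interpolates the components linearly between
bracketing snapshots; the spatial-SD-of-speed layer uses the nearest
snapshot, consistent with its half-hourly resolution. Component-wise
interpolation and resampling (bilinear, 300 m to 50 m) avoid the speed
inflation that interpolating speeds across a direction shear would cause.

The stratification index $\log_{10}(h/U^3)$ compares depth to the cube of
the tidal current amplitude: low values are tidally mixed, values near 2.75
mark frontal boundaries, 2.75–3.5 seasonally stratified, above 3.5 strongly
stratified (`stratification_regime()`). Because $U \to 0$ at slack water,
the current is floored at 0.01 m/s before cubing; the floor is a parameter.
`mean_stratification()` uses the cycle-mean speed instead of the
instantaneous one.

Temporal covariates are circular: tidal state is the signed hour offset to
the nearest high water (period 12.42 h), and the lunar index the signed day
offset to the nearest neap date (period 14.77 d), negative before, positive
after. One neap per half spring–neap cycle is used; neap dates derived from
a tide table have day granularity, so sub-day lunar periodicity holds only
when neap instants are supplied exactly (the synthetic generator's tide
tables do this in tests).

## Core areas by kernel density

Density surfaces use the fixed bivariate-normal kernel with a full 2x2
bandwidth matrix $H$ chosen by smoothed cross-validation (SCV): the
criterion combines the exact integrated-variance term
$(4\pi)^{-1}|H|^{-1/2}$ (scaled by the effective sample size when weights
are present) with a pairwise bias term built from Gaussian convolutions at
$2H+2G$, $H+2G$ and $2G$, where $G$ is a normal-scale pilot on the weighted
covariance. The minimiser is found over a log-Cholesky parameterisation,
which keeps every iterate symmetric positive-definite; below 25 points the
normal-scale plug-in is returned instead and flagged in the `method`
attribute. Tests pin the optimizer against a brute-force grid search of the
same criterion.

Fairness across sectors is handled *before* smoothing: effort is balanced
by keeping only scan periods with simultaneous coverage from every sector
and drawing the same number of scans per sector (seeded), and sightings in
sector overlaps receive weight 0.5 so double-surveyed water does not count
twice.

Percent-volume contours rank cells by density and take the smallest cell
set reaching each volume fraction; the 50% region is the conventional core
area. Areas are cell-count areas (ties are not allowed to inflate a
region), polygons are traced on the cell mask for export, and land is *not*
excluded by default, matching raster percent-volume semantics; a post-hoc
land mask is a renormalisation the user can apply deliberately. Surface
comparison between species uses Pearson correlation across shared cells.

## The habitat model

Sightings are modelled as an inhomogeneous Poisson point process (IPP) over
the surveyed space–time, with log-intensity additive in environmental
covariates. The IPP likelihood is approximated by *infinitely weighted
logistic regression* (IWLR): sightings are response 1 with case weight 1,
and uniform "availability" points — two per ten-minute scan, drawn uniform
by area over the scan's sector out to its inflection radius
($r = R\sqrt{u}$, bearing uniform) — are response 0 with case weight
$W = 1000$. As $W \to \infty$ the logistic slope estimates converge to the
IPP coefficients; the tests verify that doubling or quadrupling $W$ moves
coefficients by less than $10^{-3}$, and that a two-stratum design recovers
its closed-form rate ratio of 3 exactly.

One subtlety the test suite documents: with a *fixed* number of
availability points per scan, the availability density (points per m²)
differs wherever the scan windows differ — across sea states (different
radii) and sites (different sector widths). Site and sea-state factor terms
absorb exactly this, which is why they belong in every fit of this family;
without them a spatial covariate that correlates with window size (depth,
here) picks up the distortion.

Smooth terms follow the standard generalized-additive toolkit (mgcv):
thin-plate regression splines (k = 10) for ordinary covariates, cyclic
cubic splines (k = 8, knots spanning one full period) for tidal state
(12.42 h), lunar index (14.77 d), aspect and current direction (360°), a
tensor-product surface (5 per margin) of the coordinates to absorb residual
spatial structure, and unpenalized factors for site and sea state
(reference level = first sorted level). Smoothing parameters are selected
by GCV within each fit; cross-validation operates across *terms*, not
smoothing parameters. Collinear covariates (|r| ≥ 0.8) are screened first,
dropping the lower-priority member of each pair under a stated priority
list that prefers the mechanistically interpretable stratification indices.

Model selection is forward, scored by leave-one-day-out cross-validated
log-likelihood (CVLL): days are the exchangeable unit because scans within
a day share weather, tide and animals. Each step adds the candidate with
the highest CVLL and stops at the first non-positive improvement; the
selection table reports retained steps and, after the stop, the remaining
candidates against the final model, each change taken against the row above
— the layout such tables conventionally use, whose bookkeeping identity
(`selection_delta_consistency()`) the acceptance tests check on reference
tables. The held-out likelihood is case-weighted by default (configurable):
the weighted sum is the quantity the IWLR approximation is built on.
Rejection of pure-noise candidates is a *statistical* property of the CV
score: with 20 day-folds the tests demonstrate ≥80% rejection; with many
fewer folds the score is noisier and the rate drops.

Effect displays (`predict_relative_rate()`) exponentiate the linear
predictor, sweeping one covariate over its observed range (a full period
for circular ones) with all others at training medians and factors at their
reference level; `rate_ratio()` is the scalar version for reported
coefficients.

## The synthetic study generator

`make_scenario()` fixes the study conditions; all generators are
deterministic given the seed. Defaults describe a desk-scale island survey
chosen to emulate the real setting: a 10 km square domain around a
2.6 x 1 km island; four platforms at 17, 17, 38 and 60 m with 90–115°
sectors; 30 days of 10-minute scans; semidiurnal high waters every 12.42 h
with a 14.77-day spring–neap envelope (amplitudes 3.2 ± 1.2 m above the
low-water datum, spring range within the ±5 m the platforms were surveyed
under); rectilinear NW–SE currents peaking near high water and capped at
3 m/s, with a wake eddy west of the island on the flood; bathymetry rising
from ~10 m at the shore to ~35 m offshore with a shallow eastern plateau
carrying a 10–20 m gully; sea state following a birth–death Markov chain on
0–4 (up 0.08, down 0.12 per 10-minute step, giving a stationary law that
favours calm states); and detection certain inside per-sea-state inflection
radii (2500/2000/1400/900/600 m), declining linearly to zero at twice the
radius. Where the emulated setting did not fix a value (the sea-state
chain, platform gap rate, eddy strength, plateau geometry) the defaults
were chosen once as field-plausible and are not tuned.

The sighting process is an IPP whose log-intensity adds a linear depth
effect (0.06 per metre about 20 m) and a cyclic tidal-state effect
(amplitude 0.6, peak at HW−3 h); the intercept is calibrated so the
expected detected count hits a target (800 by default), which keeps
scenarios comparable across seeds. Observed bearings and reticles are
quantized (1°, half reticle) to reproduce the stepped-distance artefact;
the truth record keeps exact positions, the intercept and the expected
count. A configurable within-scan re-sighting rate exercises the
de-duplication rule.

What the synthetic tests establish: geometric correctness of geolocation
(closure through quantization to within the reticle step), exactness of the
covariate formulas, consistency of the inflection estimator in its stated
regime, mass conservation and contour geometry of the KDE, and recovery of
IPP coefficients within ±15% in ≥90% of a 20-seed battery sized to ~1500
retained presences. What they do not establish: robustness to observer
heterogeneity, misidentified species, responsive movement, weather-correlated
animal behaviour (which would confound the sea-state factor), or current
fields less smooth than the harmonic construction — on real data those
remain the analyst's responsibility.

## Problem sizes and determinism

Unit tests run on grids of at most 260 x 260 cells and studies of 16–24
days; the recovery battery uses 20 seeds of the default scenario at a
4000-presence target (~1500 after filtering), and the selection property 50
replicates of n = 2000 — sizes chosen so the whole suite completes in a few
minutes on one core while leaving the Monte Carlo margins comfortable.
Every stochastic step takes an explicit seed (scenario seed, availability
seed, effort-balancing seed), and seeded functions restore the caller's RNG
state, so pipeline stages are rerun-stable byte for byte.

## Known limitations

* The broken-stick inflection estimator overshoots smoothly-declining
  detection (see above); radii should be read as conservative bounds.
* SCV bandwidths use a normal-scale pilot rather than a full plug-in
  pilot stage; for the point counts of monthly core-area maps (tens to a
  few hundred sightings) the difference is well inside the contour-area
  tolerances tested.
* Neap dates from tide tables are day-resolution; analyses needing sub-day
  lunar phase should supply neap instants directly.
* The IWLR approximation shares the usual availability-design caveat:
  inference is conditional on the sampled availability set; the per-scan
  construction plus site/sea-state factors handle effort heterogeneity, but
  strong within-scan detection heterogeneity beyond the inflection model is
  not represented.
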