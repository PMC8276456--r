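---
title: "Methods: spatial statistics of foci within chromatin domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics of foci within chromatin domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models, conventions and
numerical choices. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The measurement model

STORM data are pointillist: an imaged structure is a table of single-molecule
localizations, each carrying unit mass. Chromatin domains (TADs) appear as
compact clouds of $10^3$–$10^4$ localizations with radii of gyration around
200 nm; replication origins, initiation sites or protein assemblies appear
as ~30 nm foci of tens to hundreds of localizations, often in a second
color channel. All cluster statistics are unweighted moments of these
points:

* barycenter $\bar r = \frac1N\sum_i r_i$;
* radius of gyration $R_g^2 = \frac1N\sum_i (r_i-\bar r)^2$ over the
  analysis dimensions (2D projected by default, 3D when astigmatic z is
  available);
* major axis, defined here as $4\sigma_{PC1}$ — four standard deviations
  along the first principal component of the member coordinates. This
  definition is a deliberate choice (the quantity is not standardized
  across software): it equals the ~95% extent of a Gaussian cluster, and
  for a uniform disk of radius $R$ its expectation is exactly $2R$, so
  half the major axis estimates the sampling radius $R$ that the analytic
  null below is expressed in. The definition is pinned in the
  configuration and recorded in outputs because the normalized statistics
  inherit its scale.
* diameter = maximum pairwise distance (computed on the convex hull for
  large 2D clusters); density = detections per convex-hull area (2D) or
  per ellipsoid-equivalent volume from the coordinate covariance (3D,
  where no exact hull volume is attempted).

## Normalized barycenter distance and its nulls

The position of a focus in its domain is summarized by
$d = |\bar r_{focus}-\bar r_{TAD}|/R$. Two normalizers are in circulation
and both are implemented: half the TAD major axis (default — it is the
sampling radius of the null derivation) and the TAD $R_g$. Every output
row records which convention produced it; the two differ by the constant
factor $(\text{major}/2)/R_g$ and preserve ranking exactly (a property
the tests assert).

A focus is attributed to its nearest TAD only when the barycenter
separation is *strictly* less than half the TAD major axis; ties between
TADs go to the lower cluster index. The strictness reading matters at the
domain boundary: foci planted exactly at radial fraction 1 sit on the
rule's knife edge, and about half of them (sometimes whole cells) are
excluded — visible in the peripheral condition of the synthetic
experiment, where surviving foci average just below 1. This is the rule
operating as specified, not a loss of sensitivity.

Against measured values the package provides random-placement
expectations. For foci uniform in a ball of radius $R$, integrating the
in-plane distance $r\cos\theta$ (latitude convention, Jacobian
$r^2\cos\theta\,d\theta$) gives mean $\frac{3\pi}{16}R \approx 0.589R$.
The other closed forms: ball 3D mean $\frac34 R$ and median $2^{-1/3}R
\approx 0.794R$; disk mean $\frac23 R$ and median $\sqrt{1/2}R \approx
0.707R$. Monte Carlo (with reported standard error) is available for all
geometry/statistic pairs and the tests confirm each closed form within
three standard errors at $10^6$ draws.

A note on a value often quoted as "about 0.71" for the random expectation:
no single convention above equals it — the in-plane-mean form gives 0.589,
the disk mean 2/3, the ball mean 3/4 — though it lies inside the span of
implemented conventions (0.589–0.794) and numerically coincides with the
disk *median*. The package therefore exposes every convention explicitly
and never asserts which one such a quote intends.

The radial density distribution (RDD) is the median (default; mean
available) of the focus localizations' distances from the TAD barycenter,
normalized by the TAD $R_g$ (default) or half major axis. Isotropy is
assumed — no polarity direction is modeled — so the radial distances are
a sufficient summary. Larger RDD = more peripheral.

## Segmentation

**Two-radius DBSCAN.** A localization is a core point when at least
`n_min` others lie within radius `r` (self excluded, threshold read as
$\ge$); core points at distance `< r_ref` connect into one cluster
(strict, "under the reference distance"); border points attach when
within `r_ref` (inclusive) of a cluster's cores, a border point reachable
from several clusters going to its nearest core (ties to the lower
cluster index). `r_ref` defaults to `r`, recovering textbook DBSCAN. The
implementation uses grid-binned neighbor search and is validated against
an independent $O(n^2)$ brute-force reference on random instances.
`auto_thresholds()` offers a scale-aware default ($r$ = 3 × the 5th
percentile of nearest-neighbor distances; `n_min` = expected neighbors
within $r$ at the global hull density, floored at 4); for known target
scales, explicit parameters are preferable and configurable.

**Voronoi density.** The tessellation route: per-point density is the
inverse of the first-rank Voronoi cell area (tessellation by `deldir`);
points above `density_factor ×` the global mean density (points /
convex-hull area) are selected, and selected points whose cells share an
edge merge into clusters. Boundary (window-clipped) cells are excluded
from selection rather than clipped to an arbitrary rectangle, avoiding a
bounding-box bias; the global mean density is computed over the convex
hull of the whole field, and both the factor and the mean are recorded.
Density factors follow the established practice for this data type: 3
for domains, 20 for origin-scale foci, 3.5 for protein clusters. The
default pipeline uses the Voronoi route for 2D data and DBSCAN for 3D,
where a planar tessellation does not apply. Higher-rank Voronoi densities
are out of scope.

## Localization, astigmatic z, and registration

Spot candidates are local maxima above a counts threshold with
brightest-first non-maximum suppression (default separation 3 px). Fits
are axis-aligned elliptical Gaussians, pixel-integrated, with a constant
offset, by unweighted least squares (Nelder–Mead then BFGS, relative
tolerance $10^{-14}$; default patch 7×7 px, gain 1 count/photon for
synthetic data). Fits are exact on noiseless model input to well below
$10^{-6}$; under Poisson noise the centroid error follows the first-order
error propagation of the least-squares estimator (the tests compute that
sandwich covariance as the oracle) and tracks the $\sigma/\sqrt{N}$
shot-noise scaling with the expected inefficiency of unweighted least
squares. Failed fits (non-convergence, widths below 0.3 px) are flagged
and dropped. The axis-aligned form reflects a cylindrical-lens geometry
aligned with the camera axes; no rotation term, no multi-emitter fitting.

z is assigned by comparing fitted widths to a calibration $w_x(z), w_y(z)$
built from a through-focus width table (≥ 10 planes; polynomial fit,
degree 6 by default — a quartic cannot follow the square-root defocus
form to nanometre accuracy over ±600 nm). Validity requires one crossing
point and single-minimum monotone branches. Lookup minimizes
$D(z) = (\sqrt{w_x}-\sqrt{w_x(z)})^2 + (\sqrt{w_y}-\sqrt{w_y(z)})^2$
(the established root-width metric) on a 2 nm grid refined by local
optimization; detections with $D$ above a cutoff (default 0.1, root-nm
scale) are rejected as unexplained by the calibration.

Drift is estimated from fiducial bead images only (no localization
self-correlation): per block of movie frames (default 500; the synthetic
workflow uses 200 with snapshots every 100 frames), bead images are
averaged and FFT-cross-correlated against the first block with parabolic
sub-pixel peak interpolation; the trace interpolates linearly between
block anchors and its ends are pinned to the snapshot range so it covers
the movie. Correction subtracts the interpolated drift per localization;
frames outside the trace are an error, not an extrapolation. Channel
registration defaults to pure translation (interlaced bright-field
fiducials imply rigid offset); affine is available for chromatic terms
and requires ≥ 3 non-collinear control points. Axial drift is out of
scope (hardware focus lock territory).

## The synthetic-data generator

The generator is the package's stand-in for raw microscopy and defines
the study conditions; its defaults are fixed, not tuned per run:

* one TAD per cell, 2500 localizations, nominal radius 283 nm — a uniform
  disk whose measured 2D $R_g$ (disk spread plus precision noise in
  quadrature) is ≈ 200 nm, the imaged-domain scale;
* 7 foci of 30 nm diameter, 200 localizations each, in a second channel,
  with 50 sparse background localizations per channel so density-based
  segmentation has a noise floor to beat;
* localization precision 20 nm lateral / 50 nm axial, applied as
  isotropic per-axis Gaussian jitter (the noise *model* is a choice; only
  the resolution scale is given by the imaging regime);
* presets: `g1_uniform` (foci uniform in the domain — the random null),
  `g1s_peripheral` (radial fraction 1), `interior` (radial fraction 0.2);
  16 cells per condition;
* frames spread over 2000 movie frames (a desk-scale movie length;
  acquisition-scale 60,000-frame movies are configuration, not code);
  camera geometry 256×256 px at 160 nm/px by default, with smaller
  windows used in the rendering tests.

The default scene is deliberately two-dimensional (uniform-disk TADs,
in-plane focus placement), matching the x/y-projected convention of the
2D segmentation route. For a disk the half-major-axis estimator is
unbiased for the disk radius, so planted radial fractions are recovered
on the scale they were planted — the parameter-recovery tests demand
$\pm 0.1$ at $d \ge 0.2$. With a 3D ball analyzed in projection the same
statistic is scaled by $\frac{\pi}{4}\cdot\frac{\sqrt5}{2} \approx 0.88$
(mean projection × normalizer ratio), which is a property of that
geometry, not an estimator defect; 3D shapes (ball, ellipsoid, Gaussian)
remain available and their $R_g$ closed forms are tested.

What the generator does *not* emulate: blinking kinetics and repeated
localizations of one fluorophore, detection-probability falloff with
depth, sCMOS pixel noise maps, chromatic aberration beyond an affine
map, polymer structure within domains, and inter-domain contacts.
Passing tests therefore validate the statistical machinery and its
conventions, not those instrument- or chromatin-specific effects.

The subsampling-robustness template is a 2547-localization disk TAD with
disk radius 223.1 nm, chosen once so the expected measured $R_g$
($\sqrt{R^2/2 + 2\sigma_{xy}^2}$) is ≈ 160 nm — the scale of a
metabolically labeled domain with sparser chemistry; halving or
quartering its localizations (30 draws each) must leave the mean $R_g$
within 1% and its spread under 2%, which sampling theory
($sd(R_g) \approx R_g/\sqrt{12n}$, shrunk by the finite-population
factor) predicts comfortably.

## Numerical and degenerate-input choices

* CSV round-trips write doubles with 17 significant digits, so
  read∘write is bit-identical; ThunderSTORM-style unit-bracket headers
  are mapped on read and their 1-based frames shifted to 0-based.
* Duplicated coordinates are retained through Voronoi segmentation by
  assigning each duplicate the label of its retained twin; fully
  collinear inputs are a geometry error.
* Cluster indices order by smallest core index (DBSCAN) or decreasing
  size (Voronoi) so labelings are reproducible; permutation invariance is
  asserted up to relabeling.
* Single-point clusters: $R_g = 0$, major axis and diameter 0, density
  undefined (`NA`); normalized statistics against a degenerate TAD are
  errors, not silent zeros.
* Significance tiers use strict cutoffs `****` < 0.0001, `***` < 0.0005,
  `**` < 0.01, `*` < 0.05 (note the nonstandard third tier); the t test
  defaults to the Student pooled form with Welch available, and no
  multiple-testing correction is applied to tiered raw P values.
* Every stochastic routine takes an explicit seed and derives per-cell
  seeds below $2^{31}$; pipeline outputs embed the resolved configuration
  so deterministic stages replay bit for bit.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
$10^6$ Monte-Carlo draws per null, 1000 planted foci per radial level
(40 cells × 25 foci), 16 cells per condition in the three-condition
experiment, 100 random DBSCAN oracle instances at $n \le 200$, 20
planted-blob seeds, 1000-frame rendered movies on 64×64 px windows.
These sizes give standard errors well inside the asserted tolerances
while keeping a full run in minutes.

## Known limitations

* The Voronoi route is 2D only; 3D data go through DBSCAN.
* Localization fitting is single-emitter; overlapping emitters in a
  frame are suppressed or mis-fit rather than deconvolved.
* The density of a 3D cluster uses an ellipsoid-equivalent volume, an
  approximation that under-reports hollow or highly non-ellipsoidal
  shapes.
* Drift correction is lateral; z drift is assumed hardware-stabilized.
* No reader exists for proprietary binary localization formats; CSV is
  the interchange.
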