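---
title: "Quantifying ASC speck assembly from single-molecule localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ASC speck assembly from single-molecule localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specktools)
```

## The measurement problem

Upon NLRP3 inflammasome activation, the adaptor protein ASC condenses from a
diffuse cytosolic pool into a single micron-scale perinuclear assembly, the
ASC speck. Single-molecule localization microscopy (dSTORM, DNA-PAINT) does
not produce pixel images of this process but *localization tables*: one row
per detected fluorophore blink, with nanometre coordinates and finite
precision. `specktools` turns such tables, together with cell and speck
segmentations, into the quantities that characterize speck assembly:
cytoplasmic oligomer cluster statistics, speck morphometrics, filament
diameters, and a per-cell pseudo-time that orders fixed cells along the
assembly trajectory.

Working with localization lists rather than images has consequences that
run through the whole package: one protein yields several localizations
(blinking), the label sits up to ~11 nm away from the protein (antibody
complexes) and may fail to bind at all in dense regions (steric exclusion)
or unbind in sparse ones (low-affinity nanobodies). The package therefore
ships a generator that simulates exactly these artifacts, so every analysis
stage can be validated against known ground truth.

## Conventions

All coordinates are nanometres in image convention: x rightward, y
downward, origin at the field-of-view top-left. Pixel (i, j) of a rendered
image covers the half-open interval
[x0 + (j-1) px, x0 + j px) x [y0 + (i-1) px, y0 + i px). Areas are reported
in square micrometres. Points on a region boundary count as inside
(deterministic tie-break). Localization tables are delimited text with a
named header; regions are a small JSON schema of labeled polygons.

## Cytoplasmic cluster statistics

Non-speck ASC is quantified two ways.

**DBSCAN.** A cluster is a group of 10--300 localizations within a 70 nm
search radius. This is implemented as standard DBSCAN(eps = 70 nm,
minPts = 10) — a point is core if its eps-neighbourhood, itself included,
holds at least 10 points — followed by discarding clusters with more than
300 localizations (blink pile-ups of single over-counted labels and
speck-fragment debris). Border points join the cluster of the lowest-index
core point that reaches them, which makes labels deterministic; the
implementation is verified against a brute-force
connected-components-of-the-eps-graph oracle in the test suite. Cluster
density is clusters per square micrometre of analysed cytoplasm (cell
polygon minus speck polygon).

**Ripley's L(r) - r.** For a rectangular ROI,
K(r) = |A| / (n(n-1)) * sum over ordered pairs of w_ij 1[d_ij <= r] and
L(r) = sqrt(K(r)/pi), so L(r) - r is zero under complete spatial
randomness. Two edge modes are provided. The default, `"none"` (w = 1),
reproduces the plain estimator; it is biased low at larger radii (about
-50 nm at r = 500 nm in a 2 x 2 um ROI), which is acceptable when the
analysis compares observed data against the built-in randomization control
(`ripley_randomization()`), because uniform re-draws at the same density
share the bias exactly. The `"translation"` mode applies the translation
correction w_ij = ab / ((a - |dx|)(b - |dy|)), which is exactly unbiased
for rectangles; absolute statements about L(r) - r (such as the CSR
property checks in the tests) use it. The maximum of L(r) - r per ROI is
the summary statistic compared across conditions.

## Speck morphometrics

For the localizations inside a speck segment:

* **Radius of gyration**: Rg = sqrt(Var(x) + Var(y)) with population
  (divide-by-N) variances — the RMS distance from the centroid. The
  convention is fixed and testable; at speck localization counts the
  difference from the N-1 variant is negligible. Metrics are restricted to
  2D even when z exists, because lateral precision is several-fold better
  than axial.
* **Eccentricity**: sqrt(lambda_max / lambda_min) of the 2x2 coordinate
  covariance matrix (the ratio of major to minor axis of the equivalent
  ellipse; 1 for isotropic clouds). Eigenvalues, not eigenvectors, carry
  the magnitude. Fewer than 3 points or a collinear cloud raise an
  undefined-eccentricity error.
* **Density**: localizations per segmented speck area.

Distributions are summarized by mean, median, histogram mode and the
*unscaled* median absolute deviation MAD = median(|v - median(v)|). A
histogram mode depends on binning, which published tables rarely state;
`summarize_values()` defaults to Freedman--Diaconis, takes the center of
the tallest bin (leftmost on ties), and reports the rule alongside the
value rather than pretending the mode is binning-free.

## Filament diameters

Filament backbones are user-supplied polylines (matching a manual tracing
workflow; there is no automatic skeletonization). Cross-section centers are
placed every 50 nm of arclength; localizations within a 50 nm slab along
the local tangent and within 150 nm of the axis are projected onto the
local normal. Each section's signed-offset histogram (5 nm bins) is fitted
with a Gaussian plus constant baseline (Levenberg--Marquardt); the
diameter estimate is FWHM = 2 sqrt(2 ln 2) sigma. Sections with fewer than
20 localizations, a degenerate spread, a non-converging fit or R^2 < 0.5
are flagged and excluded. Medians are taken per filament, then across
filaments.

The measured FWHM contains the label: a primary/secondary F(ab')2 complex
adds about 11 nm on *each* side. The headline corrected thickness is the
linear subtraction `median FWHM - 2 epsilon` (floored at zero with a
warning); with the published median of 37.1 nm and epsilon = 11 nm this
gives 15.1 nm, matching the reported ~15 nm actual thickness. How
localization precision should enter this correction is a modeling choice
on which reasonable analysts differ, so the quadrature-deconvolved
alternative sqrt(FWHM^2 - (2 epsilon)^2 - (2.3548 sigma_loc)^2) is emitted
alongside, with the precision used, rather than silently folded in.

## Pseudo-time

Fixed cells caught at different assembly stages are ordered by
**pseudo-time**: the fraction of a cell's localizations that lie inside
its speck segment. This is an ordering proxy, not physical time; it is
justified by live-cell observations of concomitant cytosolic depletion and
speck growth. Localization counts (not widefield intensity) are the
currency because they are the more reliable measure of ASC amount.

Two corrections precede cross-day comparisons:

* **Day calibration** (`day_calibrate()`): per measurement day, the
  least-squares slope of widefield intensity vs cell area is rescaled to
  the maximum slope across days, then the slope of localization count vs
  (calibrated) intensity is rescaled the same way, in that order. Only
  slopes are rescaled — the quoted procedure speaks of slopes only, so
  intercepts are left alone. Values are calibrated in place, which makes
  the operation idempotent; days with fewer than two cells or a
  non-positive slope are dropped with a warning rather than silently
  distorting the rest.
* **Cell-area normalization** (`normalize_by_cell_area()`): larger cells
  contain more ASC and build larger specks, so per-cell quantities are
  regressed on cell area and `slope * area` is subtracted. The residual
  least-squares slope is zero to numerical precision, which the tests
  assert at 1e-9.

For structural comparison along pseudo-time, specks are grouped into bins
(equal-count tertiles by default; equal-width is available since the
published binning is unstated), translated so the center of mass
(unweighted mean of the reference channel's localization coordinates) sits
at a common origin, rendered (10.6 nm pixels, 1 px Gaussian blur) and
summed per bin. In dual-color data both channels move by the
reference-channel shift, preserving inter-channel structure. Horizontal
and vertical cross-sections through the origin are averaged over a
9-rendered-pixel band.

## The synthetic scene generator

`simulate_scene()` produces ground truth plus localization tables with the
statistical structure the analysis assumes. Per cell: a polygonal cell
outline (Gaussian radius, mean 7 um, SD 0.7 um, mild shape irregularity);
a total emitter count Poisson-distributed around 25 emitters per um^2 of
cell area, making ASC content proportional to cell area with constant
concentration; a recruited fraction f drawn uniformly on [0.2, 0.95) for
stimulated cells (recruitment below ~20% is essentially never observed in
speck-containing cells), or 0 for unstimulated ones. A fraction f of the
emitters forms the speck: a dense core with radial density
rho(r) ~ (1 + r/r0)^(-alpha) truncated at the core radius
R = 0.032 sqrt(cell area), plus 0--10 filaments (uniform length
100--500 nm, 15 nm true diameter, capped at 30% of speck emitters). The
remaining emitters are cytosolic: 30--90 oligomer disks (12 nm diameter,
1 + Poisson(3) emitters each) and monomers.

The profile defaults are r0 = 150 nm and alpha = 2, chosen at design time
from the analytic core amplitude: with alpha = 2 the center-to-rim density
contrast is (1 + R/r0)^2 (roughly 13-fold at the default geometry), and
the core-center amplitude spans about 8,000--39,000 emitters/um^2 as f
runs over [0.2, 0.95). A flatter alpha = 1 profile has only ~4-fold
contrast — too flat for any fixed density threshold to stay between the
core-center and core-rim densities across that amplitude range, i.e. too
flat to sustain a dense-core/less-dense-periphery distinction for every
stimulated cell.

**Probes.** Each probe binds each emitter with a Bernoulli probability
gated on the local ground-truth density (a two-level gate, the simplest
model that reproduces the observed two-region labeling): the *antibody*
preset (11 nm label, sigma_xy = 12 nm, channel AF647) binds at 0.8 below
12,000 emitters/um^2 and 0.25 above — sterically excluded from the core
center, and increasingly so as the speck densifies with f, which is what
makes late-pseudo-time sum projections ring-like; the *nanobody* preset
(2 nm label, sigma_xy = 21 nm, channel DL755) binds at 0.9 above
4,000/um^2 and only 0.2 below — core-penetrating but washed out of the
dilute cytosol and core rim. The thresholds sit inside the analytic
amplitude range above, so the antibody gate activates in the upper f range
while the nanobody gate is active in every stimulated cell. Bound labels
sit at the emitter plus a uniformly random 2D direction times the label
size, blink a geometric number of times (mean 5, support >= 1 — the
standard minimal blinking model), and each blink lands with isotropic
Gaussian precision noise. Three measurement days apply multiplicative
intensity scales (1, 0.8, 0.65) and localization efficiencies (1, 0.85,
0.7), exercising the day-calibration step.

The generator returns tight convex-hull speck segmentations (core disk
plus filament tips, 100 nm margin), emulating manual segmentation that
hugs the structure; a bounding-circle segmentation was tried first and
rejected because its area is dominated by the longest filament, which
swamps the density--pseudo-time relation with segmentation noise that a
human segmenter would not produce.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: camera/PSF-level frame formation,
localization fitting and drift (inputs are assumed drift-corrected);
photophysics beyond per-label blink counts (no kinetics, no frame
correlations); 3D structure (all geometry is 2D); real probe affinities
inside a speck, which are unknown — the two-level gate and its thresholds
are a model, not estimates of the real system; and chromatic aberration
beyond an affine map. Parameter-recovery results on synthetic scenes show
the *pipeline* is correct and sensitive, not that the biological values
are right.

## Numerical choices and degenerate inputs

* Rendering kernel truncated at 6 sigma and renormalized to unit sum, so
  interior renders conserve localization count to < 1e-6.
* Point-in-polygon: vectorized even-odd ray casting with an explicit
  on-segment test (tolerance 1e-9 nm) so boundary points are inside.
* Affine estimation: QR least squares; fewer than 3 pairs or a collinear
  source configuration (second singular value below 1e-9 of the first) is
  a degeneracy error.
* Core radii are drawn by inverse-CDF interpolation on a fixed
  2048-point grid — deterministic given the seed stream.
* Gaussian profile fits use bounded Levenberg--Marquardt
  (`minpack.lm::nlsLM`); non-convergence flags the section instead of
  failing the filament. Rigid-transform invariance of the fitted FWHM is
  limited by the optimizer's convergence tolerance (~1e-7 relative), not
  by the geometry.
* Empty localization tables cluster to zero clusters (not an error);
  Ripley requires n >= 2 and max radius <= half the shorter ROI side;
  single-point specks have Rg = 0 and undefined eccentricity.
* Pseudo-time bin edges from tied quantiles are collapsed; an
  all-identical pseudo-time vector falls back to a single [0, 1] bin.

## Problem sizes

The test-suite and acceptance-script scenes use 50 stimulated cells
(~1e6 localizations over two channels) and 12 unstimulated cells — enough
cells that rank correlations above 0.9 and fractions at the 95% level are
meaningful, while a full run stays in the minutes range. Filament
phantoms use 1e4 labels against a 1e7-sample forward Monte-Carlo oracle;
CSR checks use 2000 points per ROI over 100 seeds. These sizes are the
package's own verification choices; scaling `n_cells` or the emitter
concentration up is only a matter of runtime.

## Known limitations

Segmentation is an input: there is no automatic cell, speck or filament
detection. DBSCAN parameters are fixed by convention (10--300 @ 70 nm) and
results — especially the absolute cluster density, which blink pile-ups
inflate — should only be compared between conditions analysed with
identical parameters and labeling. Pseudo-time orders cells but does not
measure rates. The eccentricity is a 2D ellipse ratio and says nothing
about axial shape. Histogram modes remain binning-dependent; treat the
reported rule as part of the statistic.
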