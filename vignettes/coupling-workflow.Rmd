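---
title: "Soil moisture-vegetation coupling coordination: models and methods"
author: "SoilVegCoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil moisture-vegetation coupling coordination: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SoilVegCoupling)
```

## The scientific problem

In semi-arid river basins, vegetation condition and near-surface soil
moisture (SM) develop together: vegetation retains moisture through
litter, shading and root structure, while moisture limits growth. A
standard way to quantify this two-way relationship over a basin raster
is to (i) map SM per depth layer from field-measured soil
physicochemistry and satellite predictors, (ii) condense several
vegetation descriptors into one composite index (VEG), (iii) correlate
the two fields pixel by pixel through time, (iv) score their joint
state with the two-subsystem coupling coordination degree (CCD) model,
and (v) rank candidate environmental drivers of the coordination map
with a Gini-impurity random forest. This package implements that
pipeline end to end, together with a synthetic basin generator that
reproduces the statistical structure each stage assumes, so the whole
analysis runs and is tested without any external download.

## Layered soil-moisture inversion

Per depth layer (0-10, 10-20, 20-30 cm), candidate predictors -- bulk
density BD (g cm^-3), capillary and non-capillary porosity (%),
nutrients, texture fractions, and band values at the sites -- are
screened by Pearson correlation with measured SM; the two-sided
p-value uses the t distribution on n - 2 degrees of freedom and the
default gate is p < 0.05. Sites are split 4:1 into modeling and
validation sets (170 sites give 136/34), keeping all depths of a site
on one side.

Three fitters share one interface:

* **SMLR** -- forward/backward stepwise on partial-F p-values with
  p~enter~ = 0.05 and p~remove~ = 0.10, the conventional defaults of
  significance-gated stepwise selection. Selection stops when no term
  enters or leaves, with a safety cap of 50 sweeps and a saturation
  guard (R^2 within 1e-12 of 1) so that exactly collinear, zero-noise
  designs terminate cleanly. Two properties are worth knowing:
  the procedure always terminates on a *gate-stable* subset (every
  included term significant at p~remove~, no excluded term admissible
  at p~enter~; the tests verify this against exhaustive enumeration),
  and each spurious candidate surviving the marginal screen still
  enters with probability near p~enter~, so the expected number of
  false inclusions grows with the candidate pool. With realistic
  pools of correlated spectral predictors the *exact* planted subset
  is therefore recovered in roughly two runs out of three, while the
  planted predictors themselves are retained essentially always; the
  test suite asserts the calibrated false-entry rate rather than
  pretending stepwise is consistent.
* **Ridge** -- the closed-form L2 solution on standardized predictors,
  with the penalty chosen by 5-fold cross-validated RMSE over a
  log-spaced grid (1e-4 to 1e3, 29 points). The zero-penalty limit
  reproduces ordinary least squares to numerical precision, which the
  tests use as an anchor alongside an independent cross-check against
  `MASS::lm.ridge`.
* **PLSR** -- NIPALS partial least squares on standardized predictors.
  The component count is picked by 5-fold cross-validation with the
  one-standard-error rule (smallest count within one SE of the
  minimum CV error); plain CV-minimum selection routinely inflates
  the count by one or two on single-factor designs, which the 1-SE
  rule corrects. With all components on a full-rank design PLSR
  equals least squares, a second exact anchor.

Validation reports R^2 = 1 - SSE/SST, RMSE, MAE and MAPE (in percent;
undefined with a warning if a measured value is zero). Model selection
takes the largest validation R^2 among candidates satisfying
RMSE < 0.05, MAE < 0.02 and MAPE in [0, 20]%; if nothing passes, the
minimum-RMSE model is returned flagged. Ties break in the order
SMLR, Ridge, PLSR.

For wall-to-wall prediction every retained predictor needs a surface:
point-measured soil properties are spatialized by inverse-distance
weighting with power 2 (a deliberate, simple choice -- kriging is out
of scope), and predictions are clipped to [0, 1] because volumetric
moisture is a fraction and the coupling model expects [0, 1] scores.

## Composite vegetation index

Seven spectral indices (NDVI, EVI, SAVI, DVI, RVI, ARVI, GNDVI; EVI
with coefficients 2.5/6/7.5/+1, SAVI with L = 0.5 and the 1.5
multiplier) are computed cellwise from the B8/B4/B2/B3 reflectances.
Cells with a zero denominator become nodata rather than infinities.

To join net primary productivity (NPP) and leaf area index (LAI), the
candidate index is chosen by three gates evaluated on the triple
(candidate, NPP, LAI): Bartlett's sphericity p < 0.05, a pairwise
correlation with NPP or LAI above 0.6, and a Kaiser-Meyer-Olkin (KMO)
measure of at least 0.5; among passers the highest KMO wins. One
caution on reading KMO values: for a small equicorrelated set the
measure does *not* tend to 1 as correlations strengthen -- for three
variables the r -> 1 limit is 0.8, because the anti-image partials
tend to r/(1+r) -- so gates near 1 would be unattainable for
three-indicator sets by construction.

The composite weights come from a correlation-matrix PCA of the
z-scored indicators: components are retained by the Kaiser rule
(eigenvalue > 1), extended while cumulative explained variance is
below 90%; retained loadings are varimax-rotated with Kaiser
normalization (the common default when the rotation is otherwise
unspecified) and component scores use the regression method,
R^-1 times the rotated loadings. Each indicator's combined
coefficient is the score-coefficient matrix weighted by the
components' shares of the *rotated* sums of squared loadings, and the
combined coefficients are normalized to sum to one. On the reference
two-component fixture (score equations 0.570/0.637/-0.367 and
-0.130/-0.245/1.159 with rotated sums 1.778 and 1.083) this yields
weights 0.3725/0.3702/0.2573 for NPP/LAI/ARVI -- the arithmetic the
acceptance script re-runs. Two degeneracies are handled explicitly:
exactly collinear indicators make the correlation matrix singular, so
score coefficients use an SVD pseudo-inverse; and a negative combined
coefficient triggers a warning while normalization proceeds over the
raw values.

At raster level the indicator grids are min-max rescaled to [0, 1]
before the weighted sum. This is a modeling decision, not a forced
one: z-scores would preserve the PCA geometry but produce negative
values, while the coupling model below needs subsystem scores in
[0, 1]. The rescaling choice shifts absolute CCD class fractions, so
it is exposed (`rescale` argument) rather than buried.

## Per-pixel rank correlation

For each basin pixel the SM and VEG series (seasonal or annual;
annual series have n = 8 points for an eight-year record) are
compared by Spearman's rank correlation: Pearson's formula applied to
mid-ranks, with the two-sided p-value from
t = rho sqrt((n-2)/(1-rho^2)) on n - 2 degrees of freedom and p = 0
at |rho| = 1. Constant series have no rank information and become
nodata. Pixels are classed as significantly positive, significantly
negative or non-significant at alpha = 0.05 on raw p-values -- the
mapping convention in this literature -- with Benjamini-Hochberg
adjustment available behind the `adjust` switch. At n = 8 the t
approximation is slightly liberal (empirical size about 5.4% at the
5% level in the suite's null simulation); the class maps should be
read accordingly, and n is reported alongside p.

## Coupling coordination degree

With subsystem scores VEG and SM in [0, 1]:

* coupling degree C = 2 sqrt(VEG x SM) / (VEG + SM), equal to 1
  exactly on the balanced diagonal and 0 when either subsystem is 0;
  0/0 (both absent) is nodata. The harmonic-mean variant
  2 VEG SM/(VEG+SM) is available (`form = "harmonic"`) for
  sensitivity analysis; it weights joint level as well as balance and
  is not 1 on the diagonal.
* harmonization index T = alpha VEG + beta SM with
  alpha = beta = 0.5 by default (equally important subsystems,
  alpha + beta = 1).
* coordination degree D = sqrt(C x T), monotone in both arguments and
  bounded in [0, 1].

D is classified into five equal-width ordinal levels on half-open
intervals (low, high]: Extreme Disorder (0, 0.2], Mild Disorder
(0.2, 0.4], Barely Coordinated (0.4, 0.6], Moderately Coordinated
(0.6, 0.8], Highly Coordinated (0.8, 1.0]. The boundary belongs to
the lower class (D = 0.8 is Moderately Coordinated) and D = 0 is
assigned to Extreme Disorder by convention, with a message. Area
proportions are computed over classified basin pixels and sum to one.

## Gini-forest driver ranking

Eight drivers -- population density, elevation, slope, aspect, mean
annual temperature, mean annual precipitation, land-surface
temperature (LST), potential evapotranspiration (PET) -- are related
to D by a CART forest. D is first discretized into the five ordinal
classes above, so the node impurity is the classification Gini index
1 - sum p_j^2; a variance-impurity regression mode on continuous D is
available behind `mode = "regression"`. Split quality is the
count-weighted impurity decrease
gain = Gini(parent) - (n_l/n) Gini(left) - (n_r/n) Gini(right)
(the unweighted child difference can go negative, which an importance
measure cannot tolerate). Importance accumulates each split's gain
weighted by the node's sample fraction -- the accumulation standard
forest implementations use; without the node-fraction weight the many
small deep-node splits dilute the shares of the strong features
toward uniformity -- and is normalized to shares summing to one.

Defaults are 500 trees, mtry = floor(sqrt(8)) = 2, minimum leaf 5,
unlimited depth, and a seeded subsample cap of 50,000 pixels.
Thresholds are midpoints between distinct consecutive values; exact
gain ties keep the first candidate in the drawn feature order, which
makes single-tree full-mtry fits bit-reproducible (the oracle tests
compare one against exhaustive split enumeration) while leaving
forest ties unbiased across features. Two calibration facts from the
suite: label-shuffled forests spread the shares evenly at 1/8 per
feature within sampling error, and with two drivers planted at equal
lead weight their combined recovered share sits near one half.
Kendall's tau summarizes ranking consistency across depth layers;
because the trailing planted weights are nearly tied, independent
forests reproduce the leading ranks faithfully but may permute the
tail, so tau is typically high yet not always exactly 1.

## The synthetic basin generator

The generator is first-class, tested code that defines the study
conditions:

* **Geometry** -- an elliptical basin with a low-order random harmonic
  boundary on a 64 x 64 grid of 20 m cells by default (cell size is a
  parameter; the working resolution of resampled satellite grids
  differs between products, so it is not hard-coded). The mask always
  covers at least half the grid and is connected.
* **Soil samples** -- 170 sites by default, three depth layers each.
  Capillary porosity (30-60%) and bulk density (0.9-1.6 g cm^-3)
  carry a north-dry/south-wet gradient; SM is the per-depth linear
  truth equation plus Gaussian noise (default sd 0.01, a realistic
  instrument-plus-model error for volumetric fractions), clipped to
  [0, 1]. The default truth coefficients are the package's reference
  inversion equations, so parameter-recovery tests double as fixtures
  of those equations. Nutrient and band ranges are chosen so the
  10-20 cm equation stays inside (0, 1) without clipping;
  clipping would otherwise bias zero-noise recovery.
* **Bands** -- ten bands (B2-B12, VH, VV) derived from a shared
  latent vegetation state with the southward gradient, a seasonal
  cycle peaking in July, and smooth spatial texture; reflectances in
  [0, 1], radar backscatter in [-30, 0] dB.
* **Coupled series** -- aligned annual SM and VEG stacks sharing one
  interannual anomaly whose sign flips between the southern and
  northern halves, so correlation mapping has a planted truth.
* **Drivers** -- eight mutually independent smooth fields scaled to
  plausible physical ranges; the latent coordination field is a
  logistic function of their standardized values with weights
  decreasing geometrically (decay 0.5) along the planted order, LST
  and PET first. Independence is deliberate: correlated drivers (for
  example, lapse-rate-linked temperature and elevation) would
  confound importance recovery, which is exactly what the generator
  must make testable.

What the generator does *not* emulate: radiative transfer, SAR
speckle, cloud morphology, spatial autocorrelation of measurement
errors, or terrain-driven hydrology. Tests passing on these synthetic
basins therefore demonstrate the correctness and calibration of the
algorithms under the assumed statistical structure -- linear truth,
independent noise, monotone coupling -- not the predictive skill of
any fitted model on real field data.

## Numerical choices and degenerate inputs

* Temporal QC: an observation is flagged below a radiometric floor or
  when it departs from the mean of its two temporal neighbours by
  more than `spikeFactor` times the neighbours' absolute difference
  (endpoints only face the floor rule); gaps are filled linearly with
  nearest-value extension at the boundaries, and a cell with fewer
  than two clean points becomes nodata, counted in a message. The
  sensor-specific cloud/snow masks of operational processing are out
  of scope; the two-parameter rule preserves the flag-interpolate-
  composite shape with thresholds in configuration.
* Winter belongs to the January/February year (December is taken from
  the preceding year), the standard meteorological bookkeeping.
* Geometry mismatches raise before any computation, naming both
  geometries.
* Rasters travel as ESRI ASCII grids (plain text, six-line header,
  row 1 = north), a format every GIS reads; values are written at
  full double precision so write/read round-trips are exact.
* Seeds fan out deterministically from one global seed to per-stage
  child seeds, so stages are reproducible in isolation and the whole
  pipeline is bit-reproducible end to end.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make the
statistical assertions sharp while keeping a full run around half a
minute: basins of 24-64 cells per side; 170 sites for recovery and
splitting checks; 100 seeds for the noisy coefficient-bias check;
500 screening replicates, eight 24 x 24 null fields for the Spearman
size check and ten 100-tree forests for the shuffle calibration;
ten seeds for planted-driver recovery. The end-to-end run in
`runAll()` defaults to a 64 x 64 basin, twelve monthly band sets,
eight annual coupled layers and a 500-tree forest.

## Known limitations

* Stepwise exact-subset recovery degrades with the size of the
  screened candidate pool (see above); the planted predictors
  themselves are retained reliably.
* The n = 8 annual correlation maps have low power and a slightly
  liberal t approximation; p-values are reported with n rather than
  gated.
* IDW spatialization ignores anisotropy and measurement error;
  fitted-surface uncertainty is not propagated into the CCD classes.
* The CCD class fractions depend materially on whether the subsystem
  grids are min-max rescaled before coupling; the package default
  (rescale) is one defensible convention, and the switch is exposed
  because the alternative changes class areas, not the ordering of D.
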