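---
title: "Line-height cyanobacteria detection and chlorophyll calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-height cyanobacteria detection and chlorophyll calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakeshape)
```

## The problem

Cyanobacteria-dominated harmful algal blooms (cyanoHABs) threaten drinking
water, recreation and aquatic life in lakes. Satellite ocean-color
instruments with 300 m resolution (MERIS, OLCI) resolve thousands of inland
waterbodies, but inland atmospheres and optically complex waters defeat the
full atmospheric correction used over the open ocean. Line-height
(spectral-shape) algorithms work directly on Rayleigh-corrected
top-of-atmosphere reflectance $\rho_s(\lambda)$: by measuring the height of
one band above or below the straight baseline through two flanking bands,
they respond to spectral *curvature* and cancel most of the smooth
atmospheric and calibration signal that contaminates absolute reflectance.

`lakeshape` implements the full analysis chain around one such algorithm,
the Cyanobacteria Index (CI): index computation and bloom-type decision,
simplified Level-3 compositing, screening of in situ chlorophyll records,
same-day satellite-to-in situ match-ups, bootstrap recalibration of the
linear CI-to-chlorophyll relationship, and log-domain validation with
trophic-state classification. A synthetic-data generator emulates the
statistical structure of a real match-up campaign so every stage is
testable without satellite downloads.

## The spectral-shape model

For a center band $\lambda$ with flanking bands $\lambda^-$ and
$\lambda^+$,

$$SS(\lambda) = \rho_s(\lambda) - \rho_s(\lambda^-) +
  \left[\rho_s(\lambda^-) - \rho_s(\lambda^+)\right]
  \frac{\lambda - \lambda^-}{\lambda^+ - \lambda^-}.$$

Two triplets drive the decision tree: $SS(681)$ over (665, 681, 709) nm and
$SS(665)$ over (620, 665, 681) nm. Strong chlorophyll-a absorption and
weak fluorescence in cyanobacteria pull $\rho_s(681)$ below its baseline,
so the index is defined as $CI = -SS(681)$, positive when a bloom is
present. Phycocyanin — the accessory pigment characteristic of
cyanobacteria — absorbs near 620 nm, depressing $\rho_s(620)$ and making
$SS(665)$ positive; its sign therefore attributes a positive CI to a
cyanobacteria-dominated bloom (`cyano`, the value reported as CI_cyano) or
some other bloom type (`noncyano`).

```{r}
s <- lake_spectrum(c(rho_s_620 = 0.015, rho_s_665 = 0.020,
                     rho_s_681 = 0.012, rho_s_709 = 0.022))
compute_ci(s)
```

Three conventions are deliberate:

* **Ties break away from detection.** $CI = 0$ exactly is `nondetect`, and
  $SS(665) = 0$ with positive CI is `noncyano`: a detection claim requires
  strictly positive evidence on both axes.
* **Masked is not nondetect.** A pixel with any contamination flag (cloud,
  mixed pixel, adjacency, snow/ice) yields the distinct outcome `masked`.
  A non-detection is evidence of low CI; a masked pixel is no evidence at
  all, and compositing and match-up construction treat them differently.
* **Exact nominal wavelengths.** Band lookup requires the canonical band
  centers (413–885 nm); there is no nearest-neighbour interpolation,
  because the triplet weights $(\lambda - \lambda^-)/(\lambda^+ -
  \lambda^-)$ are tied to the instrument's band plan.

Spectral *amplitude* can be factored out for display and comparison by
normalizing each spectrum by its trapezoidal integral over 400–754 nm
(`normalize_spectrum()`; integration actually runs over the measured bands,
413–754 nm, as no band exists at 400 nm). The result, in nm$^{-1}$, is
invariant to scaling of the input.

## From CI to chlorophyll

Two linear models convert CI to chlorophyll-a:
`chl_t16()` ($4050 \times CI + 20$, a regional model for hypereutrophic
Florida lakes whose 20 µg/L intercept reflects a background of
non-cyanobacteria chlorophyll, applicable above roughly 20 µg/L) and
`chl_bs()` ($6620 \times CI_{cyano} - 3.1$, a bootstrap-derived model for a
wide range of lake conditions). Negative retrievals are *removed*
(returned `NA` and counted), not clamped to zero: near-zero retrievals sit
at the edge of the models' validity and clamping would silently fabricate a
concentration.

## Screening in situ records

Discrete-sample chlorophyll databases mix near-surface routine samples with
deep casts, laboratory QC entries and replicates. `filter_records()`
applies six screening rules (depth ≤ 0.5 m and present; 0 ≤ chl ≤ 2000
µg/L; start date = end date; whitelisted sample type; replicate removal on
identical date/time/location/depth, keeping the first occurrence; shore
distance > 300 m to avoid land-contaminated and optically shallow pixels)
plus an `unparseable` catch-all, and returns a full audit whose per-rule
counts always balance against the input count.

Each rule's predicate is evaluated on the complete input table — in
particular, duplicate status is decided once, on input order — so the
surviving *set* is invariant to rule ordering and only the attribution
(first failing rule, in the order above) depends on it. Boundary
conventions: depth exactly 0.5 m survives (the rule discards "> 0.5 m"),
shore distance exactly 300 m is discarded (the rule retains "> 300 m"),
and chlorophyll exactly 0 survives filtering but is excluded later at
pairing, where log-domain metrics require positivity.

`distance_to_shore()` computes the minimum Euclidean distance to the lake
polygon's boundary, either in projected meters or from lon/lat under a
local equirectangular approximation (exact meridian scale, one
cos(latitude) parallel scale at the polygon's mean latitude — sub-meter
error at lake scale). `match_same_day()` then pairs surviving records with
valid (unmasked, `cyano`) satellite values on the same UTC calendar date —
satellite files are UTC-dated and no sub-daily time window is defined.

## Bootstrap recalibration

`split_matchups()` holds out a random 20% evaluation set (training size
`floor(0.8 N)`, so 1738 pairs split 1390/348). `bootstrap_fit()` then
resamples the training pairs with replacement `n_iter` times (default
1500), fits ordinary least squares $Chl = a \cdot CI_{cyano} + b$ on
untransformed values in each iteration, and reports the coefficient means,
the full draw vectors, and 95% intervals.

Design choices made where several defensible options existed:

* **Estimator.** Plain OLS on linear-scale values, because the target
  relationships are plain linear forms; no robust or log-scale variant is
  offered.
* **Interval construction.** Percentile (2.5th/97.5th of the draws) is the
  primary interval; a symmetric normal-approximation interval (mean ±
  1.96 sd) is stored alongside, since published coefficient uncertainties
  are often printed as symmetric ± values and the two agree when the draw
  distribution is near-Gaussian.
* **Resample size** equals the training-set size (standard nonparametric
  pair bootstrap).
* **Degenerate resamples** (zero CI variance) have no defined slope; they
  are redrawn and counted, and ≥ 10% redraws is an error because it
  signals near-degenerate data rather than bad luck.
* **Reproducibility.** Each stochastic function takes one explicit seed
  and restores the caller's RNG state, so split and bootstrap are
  independently reproducible and identical inputs give bit-identical fits.

`predict_with_bounds()` propagates coefficient uncertainty to predictions
as the min/max over the four corner combinations of the slope and
intercept bounds — an envelope that necessarily widens as predicted
chlorophyll grows.

## Validation in the log domain

Chlorophyll spans four decades with multiplicative, heteroskedastic
errors, so mean-square statistics are avoided in favour of geometric-mean
metrics computed in $\log_{10}$ space and converted back:

$$bias_{log} = 10^{\operatorname{mean}(\log_{10} M_i - \log_{10} O_i)},
\qquad
MAE_{log} = 10^{\operatorname{mean}\left|\log_{10} M_i - \log_{10}
O_i\right|}.$$

Both are dimensionless factors: a bias of 1.3 means the model runs 30%
high on average, and MAE (always ≥ 1, and ≥ max(bias, 1/bias)) of 1.2
means 20% misfit in either direction. `trophic_category()` classifies
chlorophyll into oligotrophic/mesotrophic, eutrophic, low hypereutrophic
and high hypereutrophic at 7, 30 and 90 µg/L. The published category
labels overlap at their endpoints ("0–7", "7–30") while the hypereutrophic
splits are phrased as "> 30" and "> 90", so intervals here are
left-closed/right-open — a boundary value belongs to the higher category —
and the breaks are configurable. `trophic_confusion()` cross-tabulates
observed versus predicted categories with row-normalized percentages
(empty rows are undefined, not zero), and `stratified_report()` computes
n/bias/MAE within observed-chlorophyll strata (all data, 0–700, 20–700,
and the four trophic ranges by default; the 20–700 row intentionally
overlaps, so row counts need not sum to the total).

## Compositing conventions

`daily_composite()` implements maximum-CI bin selection: per cell, the
contributing scene with the highest CI_cyano supplies *both* the CI and
all reflectance bands, keeping each cell's composited spectrum physically
consistent with its index. Non-detections score zero for selection and
masked cells are excluded; ties keep the earliest scene, which makes the
operation idempotent. `temporal_composite()` averages daily composites
over 7-day, rolling 28-day, monthly or seasonal windows. Two conventions
are defined here because the named windows do not define themselves: 7-day
windows run Sunday–Saturday (centered on Wednesday) and seasons are
meteorological (DJF/MAM/JJA/SON). Whether a temporal CI mean should
include non-detections as zeros materially changes magnitudes: the default
averages *detected* values only (mean bloom intensity when present), and
`include_nondetect = TRUE` switches to the bloom-frequency-weighted
alternative. Per-cell member counts are stored for both CI and
reflectance. Scenes serialize to netCDF with one variable per band, a
CI_cyano variable and a separate state variable, so non-detections survive
a round trip distinct from masked cells.

## What the synthetic data emulate

`sim_config()` fixes the generator's study conditions:

* **Match-up structure.** 1738 pairs; true chlorophyll log-normal with
  median 45 µg/L and log-sd 0.958 (chosen so the mean is ≈ 71 µg/L,
  matching the right-skewed concentration histogram such campaigns show),
  clipped to [0.5, 832] µg/L; satellite CI placed exactly on the
  generating line $CI = (Chl - b)/a$ with $a = 6620$, $b = -3.1$.
* **Noise.** In situ chlorophyll carries multiplicative log-normal noise
  with $\sigma = 0.2$ in $\log_{10}$ units. The log-domain perturbation is
  drawn as $\varepsilon \sim N(-\sigma^2 \ln 10 / 2,\ \sigma)$ — *mean-one*
  in the linear domain rather than median-one. This is the generator's one
  subtle design choice: with median-centered noise,
  $E[Chl\,|\,CI] = e^{(\sigma \ln 10)^2/2}\,(a \cdot CI + b) \approx
  1.11 \times$ the generating line at $\sigma = 0.2$, so the linear-scale
  OLS used in calibration would converge on a slope ~11% above the
  generating one and parameter-recovery tests would measure that bias, not
  the estimator. Mean-one noise makes OLS unbiased for the generating
  coefficients, which is the property the recovery and coverage tests
  exercise.
* **Spectra.** `make_spectrum()` is a declared closed form, not radiative
  transfer: a linear (hence curvature-free) baseline, a 681 nm depression
  and 709 nm peak in a fixed 1:9 split of the target line height, and a
  620 nm phycocyanin depression scaled by the cyanobacteria fraction. Its
  only contract is exact invertibility through the spectral-shape algebra:
  at `cyano_fraction = 1` the noiseless spectrum returns
  $CI_{cyano} = (chl - b)/a$, so chlorophyll round-trips to 1e-6 relative
  error.
* **Records and scenes.** `simulate_insitu_records()` plants violations of
  each filter rule at configurable rates and labels every record with its
  expected first-failing rule, giving the filter an exact per-record
  oracle; `make_scene()` paints circular bloom patches (overlaps resolve
  to the larger chlorophyll) on non-detect water with optional random
  masking.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: bio-optical variability and community
composition (all cyanobacteria signatures are one parametric family),
atmospheric/adjacency artifacts in $\rho_s$, CI retrieval noise (noise
enters through the in situ side only), spatial correlation of blooms
within a scene, and the sampling biases of real monitoring networks
(station placement, seasonal effort).

## Problem sizes and numerical tolerances

The test suite exercises the pipeline at the scale the analysis is
designed for: match-up sets of 1738 (split 1390/348), bootstraps of 1500
iterations, and a 200-run coverage study of the bootstrap intervals at
$\sigma = 0.2$ — sizes chosen to match the study conditions while keeping
the full suite under a few minutes on one CPU. Coverage of the generating
slope by the percentile interval is required to land in the 90–99% band
around the nominal 95%: pair-bootstrap percentile intervals undercover
mildly under strong heteroskedasticity and a heavy-tailed regressor, which
is expected behaviour, not a defect. Exact identities (spectral-shape
algebra, audit conservation, composite selection) are asserted to 1e-12;
round-trip inversions to 1e-6; hand-derived reference values to the
precision they were derived at.

## Known limitations

* The Rayleigh correction, contamination-flag algorithms and land masking
  are consumed as inputs, never computed.
* Grids are regular lat/lon (Plate Carrée) only; no integerized-sinusoidal
  binning or reprojection.
* Polygon shore distance assumes single outer rings (no holes or
  multipolygons) and Euclidean geometry after local projection.
* The bootstrap offers no stratified or blocked variants, and the split no
  stratification — appropriate for exchangeable match-ups, not for data
  with strong regional clustering.
* Published model coefficients are carried with symmetric ± bounds as
  printed; reproducing them from real data requires the original match-up
  file, which the package does not ship.
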