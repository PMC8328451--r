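---
title: "Methods: snow-free patch mapping and winter habitat selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: snow-free patch mapping and winter habitat selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowsel)
```

## The problem

Wintering mountain reindeer can either dig feeding craters through the
snowpack or travel to the wind-blown ridge patches that stay bare. Testing
whether animals actually concentrate on snow-free ground requires (i) a map
of that ground at the resolution of satellite imagery, calibrated against a
far finer snow reference, and (ii) selection statistics that compare
observed GPS use with what proportional availability would predict. This
vignette documents how `snowsel` implements both, which choices were open,
and what the synthetic tests do and do not demonstrate.

## Rasters and conventions

All layers live on a lightweight planar grid (`grid_create()`): a matrix
plus top-left origin and cell size in meters, `NA` for nodata. Cells are
half-open — a point on a shared edge belongs to the cell right/below — so a
position maps to exactly one cell. Nodata propagates through cellwise
operations; aggregations drop nodata cells from both numerator and
denominator. I/O uses the headered ASCII grid format, tracks are CSV with
ISO-8601 UTC timestamps, patches export to GeoJSON.

One deliberate inversion: the package stores the snow-**free** fraction per
coarse cell (0 = fully snow-covered, 1 = fully bare), so the 80/50/30%
patch thresholds read directly; the snow-covered convention used in some
reference data is simply `1 − x`.

## Snow-free reference and indices

* **35 cm rule.** A fine cell is snow-free when depth ≤ 35 cm — the depth
  at which laser-intensity imagery renders alpine ground "black" (bare).
  The rule is inclusive at exactly 35 cm; the classification is a pure
  function of the depth layer.
* **NDSI** = (green − SWIR)/(green + SWIR), averaged cellwise over scenes
  with nodata skipped; the mean of several noisy acquisitions tracks true
  snow cover better than any single scene, which the test suite verifies by
  Monte-Carlo on the generator.
* **TPI** is cell elevation minus the mean of a square moving window
  (default 30 m). The focal cell is excluded from the neighborhood mean —
  the common convention — behind a flag, since reference implementations
  differ and neither choice is canonical. Windows truncate at grid edges
  rather than padding with invented elevations. Implemented with
  summed-area tables, so cost is independent of window size.
* **Aggregation** requires the coarse grid to nest exactly `factor²` fine
  cells; coarse cells straddling the reference edge are simply not produced
  (full fine coverage is required per reference cell).

## Snow-fraction calibration

Reference cells are heavily skewed towards snow-covered, so calibration
rows are drawn with `balanced_sample()`: about the same number of cells per
10%-wide fraction bin. The response is curvilinear in both predictors with
a threshold effect in TPI, so the built-in learners are flexible: a
penalized thin-plate spline regression (mgcv) and gradient-boosted stumps
(xgboost, depth-1 trees); any learner honoring the `fit`/`predict` contract
can be supplied, and a plain linear learner ships for baselines and tests.
Evaluation is 5-fold cross-validation repeated 5 times (25 resamples),
folds stratified on response deciles to mirror the balanced design, scored
by out-of-fold R². The two best learners by mean CV R² (ties towards fewer
hyperparameters) are refit on all rows and averaged unweighted, clipped to
[0, 1]. On synthetic data the package does **not** attempt to reproduce any
particular published R² — that would require the original airborne-laser
and satellite data; instead the tests check structural properties: 25
resamples, correct sign of the NDSI–fraction correlation (negative, since
NDSI rises with snow cover and the response is the snow-free fraction), and
that the ensemble generalizes at least as well as the weakest learner.

## Patches

Thresholding is inclusive ("50% or more"). Connected components are labeled
via an adjacency graph (igraph); the default is 8-connectivity because
wind-scoured crests often run diagonally across grid axes, with
4-connectivity available — published patch counts do not pin down the rule,
so neither option is asserted as canonical. Between-patch distance is the
minimum **edge-to-edge** Euclidean gap between cell squares (exact:
per-axis center offsets shrink by one cell size, floored at zero), because
"distance between patches" naturally reads as gap width; centroid mode is
available. A centroid-distance lower bound prunes the pairwise search
without changing the minimum. Exclusion polygons remove cells whose
*centers* fall inside — the usual rasterization rule — then relabel and
report the excluded share. Distance-to-snow-free surfaces use an exact
Euclidean distance transform (EBImage), optionally after removing patches
below a minimum area (e.g. 1,800 m², a median patch, when the predictor
should mean "distance to a patch worth visiting").

## Selection against proportional availability

The null model is proportional use: expected on-patch positions =
N × areal availability fraction, kept real-valued (rounding is display
only). The 2×2 used/available table yields the odds ratio with Wald
interval on the log scale and a two-sided normal p-value. Zero cells error
unless the Haldane–Anscombe +0.5 correction is explicitly requested —
never silently. Diel periods tile each day exactly: morning and evening are
the ±1 h windows around sunrise and sunset, day and night the remainders,
all half-open on the right; sunrise/sunset come from standard solar
geometry (zenith 90.833°), and polar dates are flagged and excluded rather
than guessed.

## RSPF estimation

Positions are first snapped to the lowest-snow fine cell whose center lies
within a 5 m buffer (GPS error is of that order, and an animal near bare
ground is best represented by it); ties go to the nearer cell, then
row-major. Availability is a uniform seeded sample of fine cells without
replacement. Predictors (SNOW, DIST, LICHEN, DEM, DEM² computed before
scaling, TPI, XCOORD) are z-scored with the sample (n−1) standard
deviation over all rows. The estimator is plain maximum-likelihood binary
regression with the complementary log-log response
`p = 1 − exp(−exp(η))` — iteratively reweighted least squares, convergence
at relative log-likelihood change < 1e-8, at most 100 iterations, standard
errors from the observed information at the optimum. This is the naive
use–availability estimator; a weighted-distribution estimator for sampled
availability is a documented non-goal, so coefficient-level replication of
any published fit is not claimed. Model comparison is by AIC with the
Δ < 2 caution flag; goodness of fit by Hosmer–Lemeshow over fitted-decile
groups (df = groups − 2, tied groups merged with df adjusted);
collinearity by variance inflation factors.

## The synthetic generator

The generator's defaults encode the study conditions the package targets:

| parameter | default | meaning |
|---|---|---|
| `extent`, `fine_cell`, `coarse_factor` | 900 cells, 1 m, 30 | 900 m × 900 m fine grid nesting a 30 m coarse grid |
| `terrain_roughness`, `terrain_relief` | 3, 7 m | power-law spectrum exponent; surface sd at the reference exponent |
| `snow_base` | 131 cm | mean late-April snowpack of the emulated region |
| `snow_tpi_gain` | 26 cm/m | scouring/deposition per meter of TPI |
| `snow_east_gradient` | −40 cm/km | drier continental east |
| `noise_sd` | 8 cm | unstructured depth noise |
| `n_scenes`, `ndsi_noise_sd` | 6, 0.08 | satellite acquisitions and their noise |
| `n_animals`, `n_steps`, `step_interval` | 5, 400, 3 h | GPS collar cadence |
| `beta_snowfree`, `n_candidates`, `step_scale` | 2, 8, 150 m | discrete-choice movement model |

Terrain is spectral (power-law) noise — one exponent controls
autocorrelation — with amplitudes scaled deterministically so the surface
sd equals `terrain_relief` at the reference exponent; there is no
per-realization normalization, so generators stay pure functions of
`(seed, config)` and the large-exponent limit (a near-constant surface) is
preserved. Snow depth is `max(0, base + gain·(−TPI) + gradient·x + noise)`
— truncation at zero enforces physical non-negativity. The *generating*
TPI uses a 120 m window, deliberately broader than the 30 m analysis
window: wind redistributes snow over whole terrain forms, and with the
narrow window no coarse cell ever reaches 50% bare. With the defaults the
coarse snow-free fractions at the 80/50/30% thresholds are about
1.2%/8%/19%, bracketing the published 1.4%/9.4%/18% for the emulated
region. Movement is a discrete-choice walk: per 3-h step, `n_candidates`
isotropic Gaussian proposals, chosen with probability ∝
`exp(β · I[snow-free])`, reflecting at the boundary so availability stays
constant without absorbing animals. No published movement model exists for
this system; β is a device for testability, not a claim about real
animals.

**What passing tests show — and do not.** The synthetic landscape has
Gaussian terrain, additive snow noise, exactly proportional NDSI response,
and a memoryless movement rule. Real data add sensor artifacts, cloud
masks, vegetation-confounded spectral signals, herd behavior, and strong
temporal autocorrelation. Green tests therefore certify the *statistical
machinery* (estimators unbiased, intervals calibrated, bookkeeping exact),
not field validity of any particular map.

## Numerical choices and degenerate inputs

* IRLS starts at the intercept matching the sample proportion; separation
  or rank deficiency aborts with the iteration trace rather than returning
  a fragile fit.
* Cross-validation resamples with constant held-out response (SST = 0) are
  flagged `NA`, not scored.
* The pipeline's RSPF diagnostics report VIFs as computed; on synthetic
  landscapes snow depth and TPI are constructed to be strongly related, so
  VIFs can exceed the < 2 guard a field analyst would demand of real
  predictors — the report shows the number, the analyst applies the rule.
* Every random operation takes an explicit seed; `run_pipeline()` writes a
  manifest (config, version, seeds) and two runs from one configuration are
  identical.

## Problem sizes

Default analyses run a 900² fine grid (30² coarse), 5 tracks × 400 steps,
calibration on ~150 balanced rows, 5,000 availability samples; the test
suite uses 300²–450² grids, 20 replicate designs of n = 5,000 for
parameter recovery, 50 replicate track simulations for null calibration,
and 100 replicates for goodness-of-fit calibration. These sizes were chosen
so the full pipeline and every property check complete comfortably on a
single CPU while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* No reprojection: all grids must share one planar georeference.
* The RSPF estimator is the naive binary-GLM form (see above).
* Selection inference assumes independent positions; 3-h GPS fixes are
  autocorrelated, so real-data intervals are anti-conservative. The
  proportional-availability null is implemented as specified; step-selection
  or autocorrelation-aware inference is out of scope.
* Exclusion handling is cell-center-in-polygon, not exact area
  intersection.
* GeoTIFF is not read or written; use the ASCII grid interchange format.
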