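# snowsel

Winter habitat-selection analysis for alpine ungulates that forage on
wind-blown, snow-free patches: mapping those patches from remote-sensing
indices, and quantifying how strongly GPS-collared animals select them.

In snow-rich mountain tundra, reindeer in winter face a choice between
digging feeding craters through the snowpack and travelling to the scattered
ridge-top patches that the wind keeps bare. Quantifying the preference for
snow-free ground — and mapping where that ground is — takes a chain of
geomatics and statistical steps that this package implements as one tested,
reusable pipeline:

1. **Snow-free reference** — classify a fine (1 m) snow-depth grid as
   snow-free at depth ≤ 35 cm and aggregate to the snow-free *fraction* of
   each coarse (30 m) satellite pixel.
2. **Snow-fraction model** — calibrate flexible regressions (penalized
   splines, gradient-boosted stumps, plus any learner honoring the
   fit/predict contract) of the scene-mean Normalized-Difference Snow Index
   (NDSI) and Topographic Position Index (TPI) against that reference, with
   balanced sampling over fraction bins, 5-fold × 5-repeat cross-validation,
   and averaging of the two best learners; predict the fraction area-wide.
3. **Patches** — threshold the fraction surface (80/50/30% scenarios),
   label connected snow-free patches (8- or 4-connectivity), apply exclusion
   polygons, and compute size and between-patch-distance statistics plus
   distance-to-snow-free surfaces.
4. **Selection** — overlay GPS positions, compare observed on-patch use
   with the expectation under proportional availability, and report
   selection ratios and odds ratios with Wald intervals,

   `OR = (used_on / used_off) / (avail_on / avail_off)`,
   `CI = exp(log OR ± 1.96 · SE)`, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`,

   overall and stratified by diel period (morning/day/evening/night anchored
   ±1 h around per-date sunrise and sunset).
5. **RSPF** — fit resource-selection probability functions: binary
   maximum-likelihood regression with the complementary log-log response
   `p = 1 − exp(−exp(η))` on used-vs-available designs (5 m lowest-snow
   snapping, z-score standardization), ranked by AIC, with Hosmer–Lemeshow
   and variance-inflation diagnostics.
6. **Synthetic data** — a landscape-and-track generator (spectral-noise
   terrain, TPI- and gradient-driven snowpack, noisy NDSI scenes, and a
   discrete-choice movement model with a known snow-free selection strength
   β) so every stage is testable end to end without any external download.

## Worked example

The selection statistic from a published winter data set: of 188,942 GPS
positions, 56,378 fell on snow-free patches (50% coverage threshold) against
17,383 expected under proportional availability:

```r
library(snowsel)
odds_ratio(56378, 188942 - 56378, 17383, 188942 - 17383)
#> Odds ratio 4.197 (95% CI 4.1206-4.2755), p = 0
```

i.e. the odds of finding a reindeer on a snow-free patch were about 4.2
times the odds implied by patch availability alone — strong, precisely
estimated selection.

The full pipeline on a synthetic landscape with planted selection
(`beta_snowfree = 2` log-odds for snow-free cells at each step choice):

```r
report <- run_pipeline(pipeline_config(synthetic = synthetic_config(seed = 42)))
report$selection$t50[c("used_on", "availability_fraction", "ratio")]
#> $used_on            [1] 354
#> $availability_fraction [1] 0.0756
#> $ratio              [1] 2.34
head(report$rspf$ranking, 3)
#>       model k      aic    delta_aic within_2
#> 1 no_xcoord 8 5834.971 0.000000e+00     TRUE
#> 2      full 9 5834.972 5.899175e-04     TRUE
#> 3   no_dist 8 5838.129 3.157707e+00    FALSE
```

The animals use snow-free cells 2.3 times more than availability predicts,
and AIC ranking flags that dropping the east-west coordinate costs nothing
on this landscape (no planted climate gradient in use) while dropping snow
depth or TPI costs hundreds of AIC units — the planted mechanism is
recovered. `report$calibration$prediction_r2_vs_truth` (here 0.98) measures
how well the NDSI+TPI ensemble reconstructs the true snow-free fraction.

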