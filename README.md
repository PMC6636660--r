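# canopycarbon

Plot-level aboveground carbon density (ACD) estimation for coniferous
forest from airborne discrete-return LiDAR, built around the area-based
approach used in operational forest carbon accounting.

Field crews can measure every stem in a handful of plots; LiDAR measures
canopy height everywhere. This package connects the two for pure
mountain-spruce stands:

* **Inventory side** — per-tree biomass from spruce allometry on
  `D²H` (stem, branch, foliage, fruit components in kg), plot AGB in
  Mg ha⁻¹, carbon via the spruce carbon fraction 0.5034, and the plot
  summaries AvgH (mean height), LorH (Lorey's, basal-area-weighted height)
  and BA (basal area, m² ha⁻¹).
* **LiDAR side** — ground classification, DEM, normalized point cloud,
  canopy height model (CHM) with inverse-distance gap filling,
  top-of-canopy height `TCH` (mean CHM pixel value per plot), height
  percentiles h25…h95, density metrics d25…d95 and canopy cover.
* **Models** — log-log OLS power laws `ACD = a·Xᵇ` for X ∈ {AvgH, LorH,
  BA, TCH}; the daisy chain `BA′ = a + b·TCH`, `ACD = a·BA′^b1·TCH^b2`;
  and the percentile multiple regression
  `ln ACD = β0 + Σ βj ln mⱼ` with backward stepwise elimination.
  Goodness of fit: log-scale R², back-transformed RMSE, seeded k-fold
  cross-validated R².
* **Mapping** — wall-to-wall prediction over a 20 m fishnet, map
  summaries and totals, two-model comparison, and the CHM pixel-size
  sensitivity experiment (1–10 m).
* **Simulator** — a synthetic spruce-stand generator (Weibull DBH,
  height-diameter curve with scatter and top damage, conical crowns) and a
  discrete-return LiDAR survey simulator, so every stage is testable
  offline with known ground truth.

## Worked example

Simulate a 94-plot campaign, extract metrics, and fit the TCH power model:

```r
library(canopycarbon)

sim <- simulate_campaign(run_config(seed = 1))
tb  <- sim$table                       # per-plot predictors + responses

tb[1:3, .(plot_id, tch, h25, d95, cc, basal_area, acd)]
#>    plot_id      tch      h25          d95        cc basal_area      acd
#> 1:       1 5.731843 5.263730 0.0010718114 0.7401747   50.58096 71.45567
#> 2:       2 3.860538 4.260132 0.0023108030 0.5351391   27.67358 37.76599
#> 3:       3 3.559577 4.396601 0.0005740528 0.5566038   30.20564 39.76563

fit_power(tb$tch, tb$acd, xname = "TCH", cv_k = 10, cv_seed = 12)
#> power fit: y = 7.2699 * TCH^1.2704  (n = 94)
#>   R2 (log) = 0.9173   RMSE (back) = 3.6773   cv R2 = 0.9151
```

Reading: a plot whose CHM pixels average `TCH` metres carries an estimated
`7.27 · TCH^1.27` Mg C ha⁻¹; TCH alone explains ~92% of the log-ACD
variation in this synthetic campaign, and the cross-validated R² barely
drops, so the model is stable. `run_pipeline()` chains the whole analysis
(all model families, two wall-to-wall maps, their comparison, and the
pixel-size experiment) into a reproducible JSON + text report:

```r
report <- run_pipeline(run_config(seed = 1), out_dir = "runs/demo")
```

A thin command-line front end lives at `inst/scripts/acd-pipeline.R`.

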