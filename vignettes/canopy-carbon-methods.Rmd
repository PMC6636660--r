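---
title: "Estimating forest carbon from top-of-canopy height: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating forest carbon from top-of-canopy height: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopycarbon)
```

# The problem

Plot-based forest inventory measures every stem's diameter (DBH, cm) and
height (m); species-specific allometry then turns those into aboveground
biomass (AGB) and, with a carbon fraction, into aboveground carbon density
(ACD, Mg C ha^-1^). Airborne LiDAR cannot see diameters, but it measures
canopy height everywhere. The area-based approach (ABA) fits a statistical
link between plot-level LiDAR summary metrics and plot ACD, then applies
that link wall-to-wall over a grid.

`canopycarbon` implements one specific ABA pipeline for pure mountain-spruce
stands and, alongside it, a stand and LiDAR survey simulator so the entire
chain is testable without field or flight data.

# Models

## Per-tree allometry and plot responses

Tree biomass components come from power laws on the combined size variable
$D^2H$:

$$W_{stem} = 0.0478\,(D^2H)^{0.8665} \qquad W_{branch} = 0.0061\,(D^2H)^{0.8905}$$
$$W_{foliage} = 0.2650\,(D^2H)^{0.4701} \qquad W_{fruit} = 0.0342\,(D^2H)^{0.5779}$$

with $D$ in cm, $H$ in m and masses in kg per tree (the coefficient sources
do not print units; these are the only units that give plausible per-hectare
magnitudes, and we state them explicitly). Plot AGB is the sum of tree
totals scaled by the exact plot area; ACD = 0.5034 AGB, the spruce carbon
fraction measured by dichromate oxidation in the same region. Trees below
the 5 cm census threshold are excluded everywhere, matching the inventory
protocol.

Plot summaries are the arithmetic mean height AvgH, Lorey's height
$\mathrm{LorH} = \sum BA_i H_i / \sum BA_i$ (basal-area weighted), and
basal area $BA = \sum \pi (D_i/200)^2$ per hectare.

## LiDAR metrics

From a classified point cloud the package derives:

* a DEM (mean ground elevation per cell, inverse-distance fill);
* a normalized point cloud (NPC): elevations minus the bilinear DEM,
  clamped at 0;
* a CHM: mean NPC height of the vegetation returns per pixel, 0 for
  ground-only pixels, IDW fill (power 2, 12 neighbours) for empty pixels;
* TCH: the mean of the CHM pixels inside a plot (400 pixels for a 20 m plot
  at 1 m resolution, with the raster origin snapped to the plot grid so the
  tiling is exact);
* height percentiles h25...h95 (linear-interpolation quantiles of NPC
  heights above a 2 m cutoff), density metrics d25...d95 (fraction of all
  returns above the given percentage of the plot's maximum height), and
  canopy cover CC (fraction of first returns above 2 m).

The density-metric and cover definitions deserve a note: the field's common
toolchains do not document a single canonical formula, so ours are declared
rather than inferred. The relative-height exceedance definition keeps every
dXX in (0, 1], which the log-transformed percentile model requires.

## Model families

All models are fitted by OLS after natural-log transformation (power laws
become linear, and the multiplicative error structure of biomass data
becomes homoscedastic):

1. **Plot power models** $ACD = a\,X^b$ for $X \in \{AvgH, LorH, BA, TCH\}$.
2. **Daisy chain** $BA' = a + b\,TCH$ (untransformed OLS), then
   $ACD = a\,BA'^{b_1}\,TCH^{b_2}$ — the two-stage route that mimics
   diameter-height allometry using LiDAR height alone.
3. **Percentile model** $\ln ACD = \beta_0 + \sum_j \beta_j \ln m_j$ over
   the eleven candidate metrics, reduced by backward stepwise elimination.

$R^2$ is reported on the log scale where the fit happens (a back-transformed
$R^2$ is also available); RMSE is computed after exponentiating the fitted
values, with no bias correction by default and Duan's smearing behind a
flag. Model stability is assessed by seeded k-fold cross-validation
(k = 10 default, k = n gives the jackknife), pooling out-of-fold
predictions into $cv\,R^2 = 1 - SSE/SST$.

### Stepwise selection and family-wise error

The retention threshold of the backward elimination is, by default,
$\alpha/m$ for $m$ candidates (family-wise $\alpha = 0.05$, Bonferroni).
This is a deliberate choice: percentile metrics are strongly collinear, and
elimination at a raw per-coefficient 0.05 keeps at least one spurious metric
in roughly a third of simulated samples. Family-wise control is what lets
the procedure converge on sparse, interpretable models of the kind the
percentile literature reports (two retained metrics out of eleven);
`family_correction = FALSE` restores the classical behaviour.

## Mapping and the pixel-size experiment

A fishnet of 20 m cells (the plot size) tiles the survey extent; per-cell
metrics are extracted exactly as for plots, models are applied per cell, and
totals are cell density times true cell area (partial edge cells keep their
clipped area). Cells without returns become nodata and are excluded from
summaries. Two maps on the same fishnet are compared by
$|T_1 - T_2|/T_1$ on their totals.

The pixel-size experiment rebuilds the CHM at 1–10 m, re-extracts TCH and
refits the TCH power model per size. The mechanism that degrades coarse
CHMs in this pipeline is worth stating: at 1 m, most pixels are purely gap
(0) or purely crown, so TCH blends canopy height with canopy cover; at
10 m, almost every pixel contains some crown returns, the gap signal
disappears, and TCH saturates toward a pure height measure with less
carbon information.

# The synthetic campaign

The simulator is the package's test bed and defines its study conditions.
Defaults emulate a 94-plot campaign of 20 m × 20 m plots in pure spruce
with about 61 census trees per plot (5734/94) and a merged pulse density of
3.43 m^-2^ with up to five returns per pulse (the survey it emulates flew
seven overlapping passes; we model only the merged cloud on a jittered
grid).

Stand structure, in detail:

* **DBH**: Weibull(shape 2.0, scale 16 cm), left-truncated at the 5 cm
  census threshold (the untruncated distribution keeps 90.7% of its mass
  above it); mean DBH ≈ 14 cm.
* **Stand-stage variation**: each plot's Weibull scale is multiplied by a
  lognormal factor (sd 0.15). Natural uneven-aged reserves are mosaics of
  stand stages; without this between-plot size signal every height metric
  would be pure noise against ACD, which is not what field campaigns in
  such forests observe.
* **Heights**: $H = 1.3 + 1.7\,D^{0.55} e^{\varepsilon}$,
  $\varepsilon \sim N(0, 0.25^2)$ — a typical-looking spruce
  height-diameter curve with the wide scatter of suppressed versus dominant
  trees plus hypsometer error.
* **Top damage**: old dominant spruce frequently carry broken or dieback
  tops; a tree loses 15–45% of its height with probability
  $\min(0.5, 0.06\,(D/16)^3)$. This concentrates height unreliability in
  exactly the trees that dominate basal-area-weighted metrics, and it is
  the feature that makes Lorey's height a poor carbon predictor here, as
  it is in real uneven-aged stands.
* **Crowns**: cones with apex at the tree top, live crown 60% of height,
  radius 0.08 m per cm DBH. Terrain is a smooth doubly periodic surface
  (amplitude 5 m around 2800 m).
* **LiDAR**: first-surface-wins ray casting against the cones and terrain;
  Gaussian ranging noise (sd 0.15 m); canopy pulses emit a ground echo with
  probability 0.5; 0.2% of pulses add a gross outlier labelled noise.

Per-tree "true" AGB uses the same component equations as the inventory
module, so plot truth and downstream fits are internally consistent.

What the simulator does **not** reproduce: real crown shapes and clumping,
occlusion beyond the first surface, scan-angle and intensity effects,
species mixtures, and the genuinely unknown error structure of field
height measurement. Passing tests therefore demonstrate the correctness and
internal coherence of the pipeline, not field-accuracy claims.

# Numerical choices

* Quantiles: linear interpolation between order statistics throughout
  (fixed for reproducibility; the field's tools differ silently here).
* IDW: power 2, 12 nearest filled cells, expanding ring search, no radius
  cap.
* Ground classification: robust z-outlier removal (10 MAD), then per 2 m
  cell a ground reference equal to the median of points within 1 m of the
  cell minimum, interpolated bilinearly; points within 0.3 m of the surface
  are ground. The bilinear reference matters: a piecewise-constant cell
  minimum loses several percent recall to intra-cell slope.
* Degenerate regressions: a constant response yields slope 0 with
  $R^2 = 0$; a constant predictor is a hard error (no silent
  pseudo-inverse).
* The master seed fans out additively to the stand, LiDAR and
  cross-validation substreams, so any stage can be rerun independently and
  the whole pipeline is byte-reproducible.

# Problem sizes used in validation

The packaged validation suite simulates 94-plot campaigns (the emulated
study's size) for the single-campaign checks and model-comparison
properties, 100 independent campaigns for the predictor-ordering and
daisy-chain equivalence properties, 50 campaigns for the pixel-size trend,
and 200 regression replicates for the stepwise-selection study. These sizes
give Monte-Carlo margins comfortably tighter than the thresholds they are
checked against.

# Known limitations

* The plot power models assume multiplicative lognormal errors; counts or
  zero-inflated responses are out of scope.
* The daisy chain refuses domains where the fitted linear link predicts
  non-positive basal area (short-canopy extrapolation).
* TCH depends on the CHM's origin snapping; mapping with a fishnet not
  aligned to the CHM grid mixes pixels across cell boundaries.
* No spatial autocorrelation modelling, no interpolation across cell
  boundaries, no machine-learning regressors: the package deliberately
  stays within the closed-form allometric framework it studies.
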