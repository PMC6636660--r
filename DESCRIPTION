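Package: canopycarbon
Title: Plot-Level Aboveground Carbon Density from Airborne LiDAR Canopy Height
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An area-based toolchain for estimating aboveground carbon density
    (ACD) of coniferous forest from airborne discrete-return LiDAR. Computes
    per-tree biomass from spruce allometry, plot summaries (Lorey's height,
    basal area, AGB, ACD), normalized point clouds, canopy height models with
    inverse-distance gap filling, top-of-canopy height (TCH) and
    height/density percentile metrics; fits and cross-validates power-law,
    daisy-chain (TCH to basal area to ACD) and percentile multiple-regression
    models; maps ACD wall-to-wall over a fishnet grid and quantifies the
    sensitivity of the TCH model to CHM pixel size. Includes a synthetic
    spruce-stand and LiDAR survey simulator so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
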