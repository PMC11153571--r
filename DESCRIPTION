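Package: rootseg
Title: Root Segmentation and Biomass Quantification for Hydroponic
    Chamber Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based three-class semantic segmentation of plant-root
    scans from hydroponic growth chambers (EcoFABs) with a 2-D residual
    U-Net, convex-hull and mathematical-morphology post-processing of
    time-series predictions, and root-biomass quantification with
    regression against scale-measured weights. Includes a synthetic
    root-phantom generator so the full pipeline can be exercised and
    validated without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    pROC,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
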