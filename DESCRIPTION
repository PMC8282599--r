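Package: endmtrack
Title: Segmental Tomography and Rejection-Risk Modelling for Corneal Grafts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reimplementation of an anterior-segment OCT analysis chain
    for corneal transplants: synthetic radial-scan phantoms with known geometry,
    per-A-scan hyperreflective band detection, RANSAC polynomial boundary fitting,
    bicubic 3D surface reconstruction, normal-ray-traced thickness maps of the
    endothelium/Descemet membrane complex (En/DM) and the full cornea over the
    central 2-mm zone, and the downstream longitudinal analysis that converts
    serial En/DM thickness into a graft-rejection risk predictor via
    time-dependent-covariate Cox regression, threshold sweeps, crossing-interval
    statistics and random-intercept trend models. Includes a calibrated synthetic
    cohort generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
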