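Package: pantherscape
Title: Landscape-Scale Habitat Modelling for the Florida Panther
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible pipeline for landscape-scale presence-absence
    habitat modelling of large carnivores, built around the Florida panther
    system. Engineers per-cell landscape covariates on a 1-km2 analysis grid
    (land cover composition, forest edge, seasonal water depth interpolated
    from gauging stations, area-weighted human density, road density), labels
    presence from filtered radio-telemetry, fits and validates a
    random-forest presence model with an equal-sensitivity/specificity
    threshold, ranks variable importance, runs stratified one-at-a-time
    sensitivity analysis, and converts predictions into habitat-area and
    carrying-capacity summaries. Includes a synthetic landscape generator
    with known ground-truth preference structure so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
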