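Package: platefit
Title: Replicate-Aware Analysis of Multi-Well Plate Assays with Dose-Response and Linear Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless analysis pipeline for end-point assays acquired in
    multi-well plates. Wells are bound into replicate sets via a numeric
    plate-layout matrix, screened for outliers with Grubbs' test, transformed
    (baseline subtraction, normalisation, scaling, in that fixed order),
    aggregated into means with a chosen variation measure (SD, SEM or 95% CI),
    and fitted with a four-parameter logistic dose-response model or a linear
    model by Levenberg-Marquardt least squares. Includes spreadsheet/CSV
    import, tabular and plot export, per-stage run logs, a synthetic plate
    simulator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    grDevices
Suggests:
    jsonlite,
    minpack.lm,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
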