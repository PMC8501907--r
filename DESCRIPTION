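Package: photofit
Title: Curve Fitting and Simulation Tools for Plant Ecophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and simulation tools for leaf-level plant
    ecophysiology. Simulates C3 photosynthesis with the
    Farquhar-von Caemmerer-Berry biochemical model (solving the
    supply-demand balance for chloroplastic CO2), and fits photosynthetic
    light and CO2 response curves, seven temperature response models,
    light respiration (Kok, Yin and Walker-Ort methods), mesophyll
    conductance by the variable J method with reliability screening,
    Ball-Berry, Leuning and Medlyn stomatal conductance models,
    sigmoidal and Weibull hydraulic vulnerability curves and leaf
    pressure-volume curves. Includes standardized column nomenclature
    with instrument-dialect translation, group-wise batch fitting,
    local sensitivity analysis, figure export and a synthetic-data
    generator for testing every fitting routine against known truth.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
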