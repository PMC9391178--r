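Package: qams
Title: Single-Marker Quantification of Multiple Analytes with Nonlinear
    Evaporative Light Scattering Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of multi-components by a
    single marker (QAMS) on evaporative light scattering detectors
    (ELSD), whose response follows a power law and is therefore
    calibrated in log-log coordinates. Fits per-analyte log-log
    calibration curves with linearity diagnostics and signal-to-noise
    LOD/LOQ estimation, computes relative correction factors (RCF) by
    six published formulas against a chosen single marker, quantifies
    sample batches by the external-standard method and by QAMS, ranks
    the RCF methods by the relative error between the two, and provides
    method-validation statistics (RSD, spike recovery, cross-instrument
    RCF suitability). A synthetic detector-response generator with known
    ground truth makes the full pipeline testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
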