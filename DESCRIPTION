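Package: assaypk
Title: Bioanalytical Assay Validation and Noncompartmental Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain of a quantitative LC-MS/MS
    bioanalytical assay and its pharmacokinetic application: weighted
    (1/x^2) linear calibration with back-calculation and calibrator
    acceptance, regulatory validation statistics (accuracy, precision,
    Matuszewski matrix effect/recovery/process efficiency with internal
    standard normalization, stability, signal-to-noise), first-order
    stability kinetics from log-linear regression, noncompartmental
    pharmacokinetic analysis (Cmax/Tmax, terminal slope, trapezoidal
    AUC/AUMC, clearance, mean residence time, steady-state volume,
    dose-normalized bioavailability), and a synthetic-data generator with
    known ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
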