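Package: gluvar
Title: Glucose Control and Variability Metrics for Continuous Glucose Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing continuous glucose monitor (CGM) traces:
    a validated long-format data contract (subject id, timestamp, glucose in
    mg/dL), projection of irregular sensor readings onto an equidistant
    day-by-day grid with gap-aware linear interpolation, a comprehensive
    catalogue of glucose-control and glucose-variability metrics (time in
    range, GMI, eA1c, J-index, M-value, GRADE, LBGI/HBGI, hyper/hypo indices,
    IGC, COGI, MAGE, CONGA, MODD, ADRR, GVP, MAG, AUC, rate of change, and
    Rodbard's SD decomposition), ambulatory glucose profile (AGP) summaries
    and reports, lasagna and time-series visualisations, a synthetic CGM
    generator for testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lubridate,
    optparse,
    purrr,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
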