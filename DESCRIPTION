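Package: mapswitch
Title: Supervisory Switching Robust Control for Delayed LPV Blood-Pressure Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, certification and simulation toolkit for supervisory
    (switching) robust control of single-parameter linear parameter-varying
    (LPV) plants with input delay, instantiated on mean-arterial-pressure
    (MAP) regulation of post-surgical hypertensive patients under vasoactive
    drug infusion.  Provides Smith-predictor based delay compensation,
    two-block mixed-sensitivity H-infinity synthesis of an LTI controller
    bank over a partition of the drug-sensitivity range, a grid-based
    Lyapunov dwell-time stability certificate with an admissible bound on
    the rate of parameter variation, a hysteresis supervisor, and a
    fixed-step closed-loop simulator with performance scoring against
    clinical specifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
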