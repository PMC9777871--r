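Package: vitalid
Title: Patient Identity Verification from Vital-Sign Streams with
    Gradient-Descent-Trained Expert Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects possible patient misidentification from routine
    operating-room vital signs (heart rate, end-tidal CO2, respiratory
    rate, blood pressure). A small rule-fact expert system with
    human-readable structure is trained per patient by a gradient-descent
    style error-apportionment procedure that only re-weights existing
    rule inputs, never creates associations. The package provides the
    network engine and its textual SF/TR/PR command protocol, readers for
    100 Hz anesthesia-monitoring CSV exports, a seeded synthetic cohort
    generator in the same file layout, a trial engine covering a full
    grid of network designs, normalization methods and baseline recipes,
    and the per-margin correct-to-incorrect metrics used to score them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
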