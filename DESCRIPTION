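Package: transwellr
Title: Bidirectional Transwell Permeability Analysis for In Vitro Blood-Brain Barrier Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns raw bidirectional transwell transport measurements into
    apparent permeability coefficients (Papp), efflux ratios and P-glycoprotein
    candidacy calls, absorption classes, mass-balance and calibration QC
    reports, and a piecewise-sigmoid lipophilicity-permeability (log D) model.
    Includes a two-compartment transwell simulator with known ground truth so
    every pipeline stage is testable end to end, reference data for twelve
    Angelicae Pubescentis Radix coumarins across an MDCK-pHaMDR monolayer, and
    a study-level orchestrator producing a reproducible report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
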