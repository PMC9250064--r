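Package: anchorsim
Title: Comparator Anchoring Bias in Vaccine Studies via Synthetic EHR Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of index-date selection
    ("anchoring") bias in observational vaccine studies. Generates synthetic
    longitudinal electronic health records in which covariate recording is
    encounter-driven, builds vaccinated target cohorts and four anchored
    comparators (matched arbitrary-date, matched visit-date, self-controlled
    prior-date and prior-visit), extracts windowed baseline covariates, and
    accounts for covariate balance with standardized mean differences.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    arrow,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
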