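Package: mcedrisk
Title: Risk-Stratified Projection of Multicancer Early Detection Test
    Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds sex-specific pan-cancer risk scores from polygenic
    risk scores (GWAS summary statistics with quality control and LD
    clumping) and conventional risk factors, fits left-truncated Cox
    proportional-hazards models on an age timescale, calibrates
    age-indexed baseline hazards to external incidence rates to obtain
    short-window absolute risks, and projects positive and negative
    predictive values of multicancer early-detection (MCED) blood tests
    across age and risk-score strata, including screening-eligibility
    grids and empirical-PPV time-window calibration. A synthetic-data
    module with known ground truth emulates cohort, genotype, and
    incidence inputs so the whole pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
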