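Package: gdistinct
Title: Re-Identification Risk Analysis of Demographic Quasi-Identifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies population uniqueness and re-identification risk for
    patient-level demographic data (date of birth, gender, hierarchical
    residence address). Implements hierarchical address geocoding into
    fixed-width surrogate ZIP codes, HIPAA-style "limited dataset" and
    "safe harbor" generalization policies, g-distinct risk statistics and
    cumulative risk curves built from equivalence-class size histograms,
    and per-region stratified uniqueness analysis. Ships a seeded synthetic
    population generator so the full pipeline is testable without access
    to protected health data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    tibble,
    stringi,
    withr,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
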