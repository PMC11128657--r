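Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FAERS-style quarterly
    ASCII extracts: multi-table ingestion and case deduplication,
    target-drug cohort extraction with synonym matching, MedDRA
    PT/SOC/SMQ aggregation, case/non-case disproportionality analysis
    with four methods (reporting odds ratio, proportional reporting
    ratio with Yates chi-squared, BCPNN information component, and an
    empirical-Bayes gamma-Poisson shrinker), a combined signal
    criterion with ranking, and Weibull time-to-onset hazard-shape
    analysis.  Includes a deterministic synthetic-report generator
    with ground-truth manifests so every stage is testable without
    access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
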