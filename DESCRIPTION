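Package: faersignal
Title: Disproportionality Signal Detection and Time-to-Onset Analysis for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for FAERS-style spontaneous
    adverse-event report archives: quarterly ASCII ingestion with
    case-level deduplication and deleted-report removal, MedDRA-style
    preferred-term to system-organ-class mapping, primary-suspect target
    population screening, four-algorithm disproportionality analysis
    (reporting odds ratio, proportional reporting ratio, Bayesian
    confidence propagation neural network information component, and
    multi-item gamma-Poisson shrinker) with an all-four consensus rule,
    Weibull time-to-onset failure-type classification, stratified
    subgroup screens with sex-difference testing, and descriptive
    reporting tables. Includes a synthetic FAERS-like corpus generator
    with planted drug-event associations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    fitdistrplus,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
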