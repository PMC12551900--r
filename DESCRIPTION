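Package: faersignal
Title: Proportional Reporting Ratio Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for comparative drug-safety analysis of
    spontaneous adverse-event reports in the FDA Adverse Event Reporting System
    (FAERS). Parses post-2012 quarterly ASCII extracts, deduplicates versioned
    case reports, assigns prostate-cancer cases to androgen receptor pathway
    inhibitor (ARPI) treatment groups, maps MedDRA preferred terms to disease
    categories, tabulates stratified report characteristics, and screens for
    safety signals with the proportional reporting ratio (PRR) and its
    log-scale Wald confidence interval. Includes a synthetic FAERS generator
    with analytically known ground-truth PRRs for estimator validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
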