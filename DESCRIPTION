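Package: pvsignal
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for the FDA Adverse Event Reporting
    System (FAERS): reads and links the "$"-delimited quarterly ASCII tables
    (DEMO/DRUG/REAC/OUTC plus deletion lists), builds a deduplicated,
    window-filtered analysis cohort restricted to primary-suspect drugs,
    computes the four standard disproportionality indices -- reporting odds
    ratio (ROR), proportional reporting ratio (PRR), the empirical Bayes
    geometric mean (EBGM) under DuMouchel's two-component gamma-Poisson
    mixture fitted to the whole drug-by-event grid, and the information
    component (IC) with gamma credibility bounds -- and applies an
    all-four-indices signal rule with minimum report counts. Ships a
    synthetic FAERS-schema generator with known ground truth (injected
    relative risks, duplicate report versions, missing demographics) so the
    whole pipeline is testable without downloading FAERS.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
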