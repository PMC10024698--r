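Package: pvsignal
Title: Disproportionality Analysis for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Signal detection for spontaneous adverse-event reporting
    databases in the style of FAERS extracts. Provides a flat report data
    model with drug-name normalization and case deduplication, 2x2
    contingency tables for drug-event pairs (overall and stratified by sex
    and age), the classical disproportionality statistics (chi-squared,
    relative reporting ratio, proportional reporting ratio, reporting odds
    ratio, information component) with Woolf-type confidence intervals, the
    Evans positive-signal rule, an inverse-problem solver that reconstructs
    contingency cells from published summary statistics, and a seeded
    synthetic report generator with known ground-truth reporting odds
    ratios for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
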