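Package: pvror
Title: Case/Non-Case Disproportionality Analysis with Reporting Odds Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal detection in spontaneous adverse-event report databases using
    the case/non-case design. Builds analytic datasets from relational Individual
    Case Safety Report (ICSR) tables, matches reaction terms against a flat SMQ-style
    term list and drug exposures against ATC code sets, and computes crude reporting
    odds ratios with Woolf confidence intervals, covariate-adjusted reporting odds
    ratios from an internally implemented logistic fit, median-split dose-effect
    analyses with a linear trend test, and cohort descriptives (time to onset,
    dechallenge/rechallenge). Includes a synthetic ICSR database generator with
    planted effects and confounding for end-to-end calibration of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
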