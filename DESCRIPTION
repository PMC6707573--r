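Package: trialcea
Title: Trial-Based Cost-Effectiveness Analysis with Bootstrapped ICERs and
    Acceptability Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-based health-economic evaluation from the
    societal perspective: per-participant costing of self-reported resource
    use (health-care services, medication, patient and family costs,
    productivity losses via the human-capital and lost-workday-equivalent
    approaches), quality-adjusted life years by trapezoidal area under the
    utility curve, symptom-free response classification, multiple
    imputation of clinical outcomes and regression imputation of cost
    aggregates, and a bootstrapped seemingly-unrelated-regression analysis
    of incremental costs and effects with cost-effectiveness plane,
    acceptability curves and sensitivity scenarios. Includes a synthetic
    two-arm randomized-trial generator with closed-form moments for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
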