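Package: riskaudit
Title: Glass-Box Auditing of Threshold Artifacts in Clinical Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits bagged, piecewise-constant additive logistic risk models by
    round-robin gradient boosting of single-feature stump learners, and audits
    the fitted component functions for two statistical artifacts of
    threshold-guided clinical practice: jump discontinuities (tested by a
    log-likelihood contrast against a locally linearized component) and
    counter-causal concave non-monotonicities (detected by changepoint analysis
    of component slope signs). Includes a treatment-by-indication simulator
    that composes untreated risk, treatment benefit and threshold adherence
    policies into observed population risk, generates patient-level synthetic
    cohorts, and quantifies the excess risk of misaligned decision thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
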