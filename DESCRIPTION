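Package: uisae
Title: Small-Area Estimation of Unintended Births and Pregnancies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the proportion and incidence of unintended births and
    pregnancies for small geographic areas from vital-records-style data. A
    survey-weighted classifier of pregnancy intendedness is trained on a
    PRAMS-like survey and applied to a birth-record file; a second model of
    the probability that a pregnancy ends in a live birth, trained on an
    NSFG-like pregnancy history, converts expected unintended births into
    expected unintended pregnancies through inverse-probability multipliers.
    Per-birth estimates are assigned to areas by point-in-polygon lookup and
    aggregated into per-area counts, percentages and incidence per 1,000
    women, with quartic-kernel density surfaces of events per square mile
    per year. Includes a synthetic vital-records simulator with known ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    ranger,
    xgboost,
    glmnet,
    nnet
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
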