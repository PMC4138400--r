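Package: gripscore
Title: Scoring and Agreement Analysis for Handgrip Force-Tracking Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring sinusoidal handgrip force-tracking trials by
    mean absolute error in percent of maximum voluntary contraction (%MVC),
    calibrating spring-loaded handgrip devices to a subject's grip strength,
    scoring Oswestry Disability Index (ODI) questionnaires on a 0-1 scale,
    and running the pre/post-intervention agreement analysis used to validate
    tracking-based motor assessment: percent improvement, Welch t-tests,
    Pearson correlation with Cook's-distance outlier screening, and
    Bland-Altman limits of agreement. Includes a synthetic cohort simulator
    that emulates graded motor impairment, session-to-session motor learning,
    responder heterogeneity after intervention, and disability-survey
    responses coupled to impairment, so the whole pipeline is testable
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
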