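Package: pdcpersist
Title: Adherence and Persistence Analysis of Ophthalmic Pharmacy Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring medication adherence (proportion of days
    covered, PDC) and treatment persistence from longitudinal pharmacy-claims
    tables, specialized to topical glaucoma therapy. Implements bottle-based
    exposure normalization for eye-drop dispensings (30 days per bottle,
    both-eyes adjustment), stockpile-aware coverage intervals, new-user cohort
    extraction with a monotherapy run-in, fixed- versus unfixed-combination
    adherence comparison, persistence episodes with a 30-day grace period,
    Kaplan-Meier persistence estimates with log-rank tests, switching-pattern
    classification, and a univariate plus stepwise multivariate logistic screen
    for nonadherence risk factors. Includes a synthetic claims generator with
    planted ground truth so the full pipeline can be exercised and validated
    without access to proprietary claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
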