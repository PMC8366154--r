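Package: prospmatch
Title: Prospective Matching to Guide Enrollment in Non-Randomized Evaluations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and stress-testing prospective
    matching-to-guide-enrollment studies, in which treated patients identified
    from rolling administrative data pulls are matched to pools of similar
    controls by coarsened exact criteria plus a standardized minimum-distance
    function, and controls are then recruited tier-by-tier in near real time.
    Provides a synthetic multi-facility cohort generator with confounded
    treatment transfer, visit-history eligibility classification, match-pool
    construction with priority tiers, a discrete-event recruitment simulator,
    standardized-mean-difference balance diagnostics, and a simulation-based
    power calculation for zero-inflated count outcomes with clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr,
    optparse
Config/testthat/edition: 3
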