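Package: gspred
Title: Predictive Probabilities for Group-Sequential Survival Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates group-sequential survival trials (piecewise-exponential
    event times, ramped accrual, asymmetric one-sided efficacy and futility
    boundaries) and converts the per-treatment-effect operating characteristics
    into Bayesian predictive probabilities of eventual success, futility stop,
    and failure. A discrete prior over proportional-hazards reductions is mixed
    with Monte-Carlo outcome tables and updated after each public "trial
    continues" announcement, so that the probability of eventual trial success
    can be tracked from outside the data monitoring committee. Ships the
    published monitoring plan of the NSABP C-08 adjuvant colon-cancer trial as
    its worked default design, and a numerical calibrator for the final-look
    significance level under alpha spending.
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
    survival,
    mvtnorm,
    optparse
Config/testthat/edition: 3
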