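Package: headcheck
Title: Bayesian Pre/Post Contrasts for Hockey Concussion Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing injury characteristics between two cohorts of
    games with skeptical Bayesian two-group binomial contrasts, built around
    the evaluation of the NHL's Rule 48 (illegal check to the head). Provides
    empirically centered Gaussian priors on the log-odds intercept whose width
    is tuned by prior-predictive simulation to a target spread of the
    between-group difference, intercept-only binomial-logit posteriors per
    cohort (deterministic quadrature or random-walk Metropolis with
    rank-normalized split R-hat convergence gating), posterior contrasts on
    the percentage-point and per-100-games scales with 70%/90% credible
    intervals and directional probability mass, a synthetic season generator
    for end-to-end pipeline testing and interval-calibration studies, and
    table/plot-data reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
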