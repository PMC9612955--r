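Package: medistract
Title: Multilevel Moderated Mediation for Motivated-Distraction Pain Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-subject experiments on task-induced hypoalgesia:
    scoring of n-back response streams with the nonparametric sensitivity
    statistic A, per-participant psychophysical and economic calibration
    (thermal temperature-response curves, an adaptive interstimulus-interval
    staircase, and a pain-for-money logistic choice model), trial filtering and
    repeated-measures ANOVA with planned contrasts and within-subject error
    bars, and a 1-1-1 multilevel moderated mediation engine that stacks
    mediator and outcome rows, estimates random a/b/c-prime paths by restricted
    maximum likelihood, computes covariance-inclusive indirect effects, and
    builds participant-level bootstrap percentile intervals.  A synthetic
    cohort generator reproduces the full factorial design so every stage of
    the pipeline can be exercised end to end without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nlme,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
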