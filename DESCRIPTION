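Package: pseudoGMM
Title: Hazard Ratio Inference from Survival Pseudo-Observations by the
    Generalized Method of Moments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms right-censored survival data into jackknife
    Kaplan-Meier pseudo-observations and estimates log hazard ratios
    through a marginal complementary log-log model, fitted either by
    generalized estimating equations, by the frequentist generalized
    method of moments (quadratic inference functions over basis-matrix
    moment expansions), or by a Bayesian generalized method of moments
    built on a moment-based pseudo-likelihood and sampled with adaptive
    random-walk Metropolis. Includes the Cox proportional hazards and
    Bayesian piecewise exponential benchmarks, a calibrated Weibull /
    uniform-censoring clinical-trial simulator, and a simulation-study
    runner reporting bias, average standard error, empirical standard
    deviation, root-mean-square error and coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
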