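Package: proirt
Title: Multilevel and Multidimensional Item Response Models for
    Longitudinal Patient-Reported Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Latent variable analysis of multi-item patient-reported
    outcomes collected repeatedly in multisite clinical trials. Items follow
    the logistic graded response model with slopes and intercepts fixed at
    calibrated item-bank values, so the latent metric is identified and the
    structural model concentrates on change over time: latent growth curves,
    correlated occasion factors with item-specific residual-dependence
    factors (two-tier structure), and uncorrelated latent difference scores,
    optionally with a site-level random intercept and latent regression on
    treatment indicators. Estimation is by Bock-Aitkin EM with two-tier
    dimension reduction or by Metropolis-Hastings Robbins-Monro stochastic
    approximation, with Richardson-extrapolation or recursive standard
    errors, Monte-Carlo marginal likelihood for model comparison,
    limited-information fit statistics (M2-based RMSEA), Wald tests,
    EAP scoring and summed-score-to-EAP conversion tables on the T-score
    metric, and a synthetic multisite trial simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
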