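Package: hclimits
Title: Prediction Intervals and Control Limits for Overdispersed
    Binomial Historical Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes historical control limits for clustered dichotomous
    endpoints (e.g., tumour counts in long-term carcinogenicity studies or
    micronucleated cells in the in vitro micronucleus test) whose
    between-study heterogeneity induces extra-binomial variation.
    Implements bootstrap-calibrated Wald-type prediction intervals under
    the quasi-binomial and beta-binomial models, posterior-predictive
    intervals from a Bayesian hierarchical beta-binomial model and a
    Bayesian logit-link random-intercept model (via 'rjags'), the common
    heuristic limits (historical range, Shewhart np-chart, mean +/- k SD),
    exact beta-binomial distribution functions, and a Monte-Carlo engine
    for coverage-probability studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    coda,
    jsonlite,
    rjags,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
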