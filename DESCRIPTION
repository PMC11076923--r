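Package: volunteerbias
Title: Quantify and Correct Volunteer Bias in Cohort Studies with
    Inverse Probability Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify and correct selection (volunteer) bias in
    a volunteer-sampled cohort using a representative reference sample.
    Fits an L1-penalized probit participation model on concatenated
    cohort and reference data, constructs normalized inverse-probability
    weights, estimates weighted and unweighted bivariate associations
    with heteroskedasticity-robust standard errors, quantifies bias
    reduction and effective sample size, and simulates collider-bias
    selection scenarios. Includes a synthetic-population generator
    (Gaussian-copula categorical variables with a configurable
    volunteer-selection mechanism) so every stage can be validated
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    methods,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
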