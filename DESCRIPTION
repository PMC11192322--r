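Package: krigsdm
Title: Species Distribution Models with Spatially Misaligned, Error-Contaminated Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting Bayesian species distribution models when
    environmental covariates are observed with measurement error at locations
    that do not coincide with the species survey locations. Implements Matern
    (nu = 1) Gaussian random field simulation, Bayesian kriging of noisy point
    observations, a logistic generalized additive mixed model with second-order
    random-walk splines and a spatial residual, and two estimation strategies:
    the standard two-stage approach that plugs kriging means into the species
    model, and a joint hierarchical errors-in-variables model that propagates
    covariate uncertainty. Includes a ground-truth simulation study of the
    attenuation (regression dilution) caused by ignoring covariate error,
    leave-region-out spatial cross-validation, and prevalence prediction
    intervals. Inference uses a nested Laplace approximation with dense
    covariance matrices, suitable for data sets up to a few thousand locations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
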