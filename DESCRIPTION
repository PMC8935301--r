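Package: ipmcor
Title: Integral Projection Models with Nonindependent Vital Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building, simulating, fitting and analysing integral
    projection models (IPMs) in which growth and reproduction are not
    independent. Dependence can be labile (breeding status as a growth
    covariate, or a Gaussian copula joining a continuous growth response to
    a binary reproduction response), temporal (a shared observed driver or
    correlated random year effects), or persistent (correlated individual
    random effects carried for life). The package discretizes projection
    kernels by the midpoint rule, computes asymptotic and stochastic log
    population growth rates (the latter by element-selection simulation),
    estimates sensitivities and elasticities by central differencing, fits
    all model variants by adaptive Metropolis-within-Gibbs MCMC with
    analytic marginalization of missing reproduction records, and provides
    an individual-based simulator for demographic panel data modelled on
    Soay sheep mark-recapture studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
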