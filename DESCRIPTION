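Package: ccemix
Title: Comparing the Carcinogenic Burden of Aerosol Mixtures via Relative
    Potency Factors and Change in Cumulative Exposure
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the carcinogenic burden of two tobacco (or
    other aerosol) products through a six-step procedure: severity
    classification of rodent carcinogenicity endpoints, quantal
    dose-response modelling with benchmark-dose (BMD) estimation and
    profile-likelihood confidence bounds, covariate (shared-steepness)
    joint fitting yielding relative potency factors (RPFs) relative to a
    reference carcinogen, geometric-mean confidence intervals for
    per-stick emissions, probabilistic Monte-Carlo computation of the
    change in cumulative exposure (CCE) between products, and a
    semi-quantitative translation of the CCE into expected health impact.
    Includes a simulation module generating binomial tumour-incidence data
    from parallel log-dose curves with known potencies and lognormal
    emission replicates, so every stage can be validated against known
    truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
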