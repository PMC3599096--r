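Package: neurokin
Title: Risk-Based Kinetic Models of Neurodegeneration from Longitudinal Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits stochastic risk-based kinetic models of neurodegeneration in
    which a biomarker of neuronal or axonal integrity (such as fractional
    anisotropy of the optic nerve) decays exponentially in cumulative,
    time-varying risk driven by a pathogenic biomarker (such as intraocular
    pressure). Provides cumulative-risk integration from irregular
    longitudinal measurements by the trapezoid rule, pooled nonlinear
    least-squares estimation of constant-rate, constant-risk, variable-risk
    and stretched-exponential (heterogeneity) models, extra-sum-of-squares
    F-tests for nested model selection, linear and risk-based models of
    secondary (transsynaptic) degeneration, histology validation statistics,
    and a reproducible synthetic-study generator emulating a longitudinal
    glaucoma experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
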