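Package: betalong
Title: Longitudinal Beta Regression for Bounded Outcome Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mixed and marginal beta regression for longitudinal outcomes
    bounded on the unit interval, such as health-related quality-of-life and
    health-utility scores.  Provides a subject-specific beta generalized
    linear mixed model with a logit-scale random intercept, fitted by maximum
    likelihood with adaptive Gauss-Hermite quadrature; a population-averaged
    beta generalized estimating equation with moment estimation of scale and
    working correlation, sandwich covariance, and adjusted marginal means; and
    a Gaussian random-intercept linear mixed model baseline.  Includes
    boundary transformations for zero- and one-valued observations with
    sensitivity sweeps, likelihood-based fit statistics and a pseudo-R-squared
    against a random-intercept-only baseline, decile residual misfit
    diagnostics, and a seedable generator for longitudinal bounded responses
    with MCAR and MAR dropout mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    pracma,
    stats,
    graphics,
    utils
Suggests:
    glmmTMB,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
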