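Package: bivtraj
Title: Bivariate Latent Growth Trajectories of Fluid Cognition and
    Functional Limitation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage structural equation pipeline for accelerated
    longitudinal panels in the style of the Health and Retirement Study:
    stage 1 fits a bivariate longitudinal factor model under strong
    factorial invariance and extracts Bartlett factor scores for general
    fluid cognition and functional limitation; stage 2 restructures the
    scores into two-year chronological age bins (ages 50-85) and fits
    univariate and bivariate piecewise-linear (spline) latent trajectory
    models with a knot at age 70, estimated by casewise full-information
    maximum likelihood with Huber-White robust standard errors.  Includes
    a synthetic panel generator with known ground truth, the FIML engine
    itself (saturated-model EM, TLI/RMSEA with noncentral chi-square
    confidence intervals, AIC), and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
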