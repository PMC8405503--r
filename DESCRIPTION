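Package: ft4pop
Title: Population Modelling of Free Thyroxine Dynamics in Treated
    Congenital Hypothyroidism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing longitudinal free thyroxine (FT4)
    measurements from newborns and infants with congenital hypothyroidism
    under levothyroxine replacement therapy.  Provides time-dependent
    normalization of multi-assay FT4 measurements to a postnatal-age
    dependent target reference range (scale, location-scale and blended
    formulas), an analytic one-compartment oral-absorption model with
    residual endogenous thyroxine production and weight-dependent volume
    of distribution, nonlinear mixed-effects estimation with log-normal
    inter-individual variability and proportional residual error,
    covariate and TSH-feedback machinery, model diagnostics (visual
    predictive checks, goodness-of-fit tables), and a multi-center
    synthetic cohort generator for simulation-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    deSolve
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
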