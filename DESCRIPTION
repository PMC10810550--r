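Package: firenb
Title: Negative Binomial and Bayesian Negative Binomial Modelling of Monthly Fire Frequency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling over-dispersed monthly fire-count time series
    with climate covariates. Provides a synthetic-data generator for monthly
    maximum temperature, rainfall and fire counts; maximum-likelihood and fully
    Bayesian Negative Binomial regression with a log link and harmonic
    (sine-cosine) seasonal terms; posterior-predictive prediction intervals;
    sequential train/test splitting with forecast metrics (RMSE, MASE, percent
    bias); a Monte Carlo simulation-study harness over a dispersion-by-length
    scenario grid; and aggregation of satellite active-fire hotspot records
    (FIRMS/MCD14DL-style CSV) into a monthly modelling table joined to monthly
    climate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    coda,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
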