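# firenb

Negative Binomial and Bayesian Negative Binomial modelling of monthly fire
frequency from climate covariates.

Monthly counts of satellite-detected vegetation fires are over-dispersed and
strongly seasonal. `firenb` is for analysts who model such count series —
fire ecologists, epidemiologists of environmental hazards, applied
statisticians — and provides, end to end:

* a **synthetic-data generator** for monthly (maximum temperature, rainfall,
  fire count) series with the statistical structure of an 18-year Kenyan
  fire/climate dataset: truncated-normal temperature TN(29.18, 2.29²) on
  [23.43, 34.82] °C, rainfall `312.692 − 7.83 × maxtemp` mm plus bounded
  uniform error, and counts from a log-link NB mean with annual harmonics;
* **two estimators** of the regression

  log μᵢ = β₀ + β₁ rainfallᵢ + β₂ maxtempᵢ + β₃ sin(2πtᵢ/12) + β₄ cos(2πtᵢ/12),
  yᵢ ~ NB(μᵢ, φ),  Var(yᵢ) = μᵢ + μᵢ²/φ

  maximum likelihood (`fit_nb()`, via `MASS::glm.nb`) and a fully Bayesian
  version (`fit_bnb()`) with N(0, 10²) coefficient priors and a
  Gamma(0.01, 0.01) dispersion prior, sampled by an in-package MCMC scheme
  (Laplace-centred multivariate-t independence kernel mixed with an adaptive
  random walk; split-R̂ and ESS diagnostics);
* **forecast evaluation**: sequential 80:20 splitting, RMSE, MASE (one-step
  in-sample naive scaling), percent bias, posterior-predictive 90%
  prediction intervals, empirical coverage, and the observed-vs-predicted
  correlation t test;
* a **simulation-study harness** over the dispersion × length grid
  θ ∈ {1.5, 5, 10, 100} × n ∈ {60, 120, 240, 360} producing wide
  scenario-by-model summary tables;
* **hotspot aggregation**: FIRMS/MCD14DL-style CSVs → monthly counts with
  mean FRP/brightness, joined to a monthly climate table into the modelling
  series (presumed-vegetation-fire filtering by type code).

See `vignettes/fire-frequency-modelling.Rmd` for the model, the sampler, the
generator's assumptions and the design decisions.

## Worked example

```r
library(firenb)

series <- generate_series(scenario_config(n = 120, theta = 1.5,
                                          n_replicates = 1), 1)
sp <- sequential_split(series, 0.8)   # first 96 months train, last 24 test

ml <- fit_nb(sp$train)
ml
#> Negative Binomial regression (log link, maximum likelihood)
#>   n = 96, dispersion phi = 25.17, logLik = -494.951
#>             estimate     se
#> (Intercept)   7.7865 0.3482
#> rainfall      0.0028 0.0005
#> max_temp     -0.0958 0.0113
#> sin_term      0.8324 0.0314
#> cos_term     -0.0253 0.0315

bnb <- fit_bnb(sp$train, seed = 76568)
bnb
#> Bayesian Negative Binomial regression (adaptive Metropolis)
#>   n = 96, 4 chains x 1000 kept draws, mean acceptance 0.46
#>   max split-Rhat 1.0051, min ESS 1022
#>   estimate     se ci_lower ci_upper
#> 1   7.7643 0.3708   7.0836   8.4956
#> 2   0.0028 0.0006   0.0017   0.0039
#> 3  -0.0950 0.0121  -0.1187  -0.0725
#> 4   0.8313 0.0329   0.7691   0.8961
#> 5  -0.0244 0.0340  -0.0892   0.0432
#> 6  23.3621 4.5855  15.4268  33.2523

pred <- predict_mean(ml, sp$test)
rmse(sp$test$fire_count, pred)                          # 32.30
mase(sp$test$fire_count, pred, sp$train$fire_count)     # 0.294
percent_bias(sp$test$fire_count, pred)                  # -0.05 (%)

set.seed(1)
pi90 <- prediction_interval(bnb, sp$test, level = 0.9)
interval_coverage(sp$test$fire_count, pi90)             # 0.88

correlation_test(sp$test$fire_count, pred)
#> Pearson correlation: r = 0.968, t(22) = 17.955, p = 1.254e-14
```

The fitted coefficients recover the generator's (7.69, 0.002, −0.09, 0.83,
−0.05) within their standard errors; both estimators agree closely, as
expected under weak priors. MASE well below 1 means the model beats the
naive last-month forecast; the negative bias sign convention means
over-prediction on average.

Pipeline equivalents (`cmd_simulate`, `cmd_fit`, `cmd_study`,
`cmd_aggregate`) write CSVs and JSON run manifests; a thin command-line
wrapper lives in `inst/scripts/firenb.R`.

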