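---
title: "Modelling monthly fire frequency with Negative Binomial regression"
author: "firenb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling monthly fire frequency with Negative Binomial regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Monthly counts of satellite-detected vegetation fires are strongly
over-dispersed (variance far above the mean) and seasonal. `firenb` models
such series with Negative Binomial (gamma–Poisson) regression on monthly
climate covariates — rainfall and maximum temperature — plus a harmonic
seasonal term, in two estimation flavours: maximum likelihood (`fit_nb()`)
and fully Bayesian MCMC (`fit_bnb()`). A simulation-study harness compares
the two on synthetic series whose structure mimics an 18-year Kenyan monthly
fire/climate dataset, and an aggregation stage turns FIRMS/MCD14DL-style
hotspot CSVs plus a monthly climate table into the modelling series.

## The model

Counts are Negative Binomial with mean $\mu_i$ and dispersion $\phi$,

$$p(y;\mu,\phi) = \frac{\Gamma(y+\phi)}{\Gamma(\phi)\,\Gamma(y+1)}
\left(\frac{\mu}{\mu+\phi}\right)^{y}
\left(\frac{\phi}{\mu+\phi}\right)^{\phi},
\qquad \mathrm{Var}(y) = \mu + \mu^2/\phi,$$

with a log link

$$\log \mu_i = \beta_0 + \beta_1\,\mathrm{rainfall}_i +
\beta_2\,\mathrm{maxtemp}_i + \beta_3 \sin(2\pi t_i/12) +
\beta_4 \cos(2\pi t_i/12).$$

The sine–cosine pair is the standard harmonic parameterisation of a smooth
annual cycle for monthly data. One modelling source describes the harmonic
argument in a form that, read literally, degenerates to a constant at integer
months; we interpret it as annual seasonality, $\sin(2\pi t/12)$ and
$\cos(2\pi t/12)$, with the period configurable. The same source writes an
additive normal error inside the link with an unspecified covariance; the
likelihood used here omits it — extra-Poisson variation is exactly what
$\phi$ carries, and the ML implementation this mirrors (`MASS::glm.nb`) has
no such term. In the ML fit $\phi$ is estimated freely; the gamma
distribution on the dispersion acts only as a prior in the Bayesian model.

### The Bayesian model

The Bayesian variant places independent $N(0, \sigma_\alpha^2)$ priors on the
five coefficients and a $\mathrm{Gamma}(f, r)$ prior on the dispersion
$\nu$. Defaults: $\sigma_\alpha = 10$ on the raw covariate scale (covariates
are deliberately not standardised so posterior estimates are directly
comparable to the ML fit and to published coefficient tables) and
$f = r = 0.01$, the conventional vague choice. Posterior summaries use
central quantile intervals (95% by default).

### Sampler numerics

The posterior over $(\alpha_0,\dots,\alpha_4,\log\nu)$ is sampled with a
mixture Metropolis–Hastings kernel:

* a **Laplace-centred independence proposal** — a multivariate $t_4$ located
  at the posterior mode (found by BFGS from the ML solution) with scale from
  the local curvature, inflated by 1.2, shared by all chains. On the
  near-Gaussian posteriors these models produce, most moves are accepted and
  draws are nearly independent. Heavy $t$ tails prevent the classic
  independence-sampler failure mode of sticking in under-covered regions;
* an **adaptive random-walk** kernel (scale tuned toward 23% acceptance
  during warmup, shape refreshed from accumulated draws) that guarantees
  irreducibility when the Laplace approximation is poor. If the independence
  kernel accepts under 30% during warmup it is refitted from the warmup
  draws. All adaptation stops at the end of warmup.

Defaults are 4 chains of 1000 warmup + 1000 kept iterations. Convergence is
flagged by split-$\widehat R$ (each chain halved, between/within-sequence
variance compared) with threshold 1.01, plus effective sample sizes via
`coda`. A non-converged `cmd_fit` run refuses to emit its summary unless
forced.

The dispersion deserves a caveat: on series generated in the default
residual-perturbation mode (below), counts are *under*-dispersed relative to
any Negative Binomial with moderate $\phi$, so the likelihood is nearly flat
in $\log\nu$ above some value and the posterior on $\nu$ is prior-dominated
and diffuse. That is a property of the data-generating process, not a sampler
defect; coefficient inference is unaffected.

## The synthetic-data generator

`generate_series()` builds a monthly table of (time, max temperature,
rainfall, fire count):

1. **Maximum temperature** — truncated normal, mean 29.18 °C, SD 2.29 °C,
   bounds [23.43, 34.82] °C (the observed moments and range of Kenyan
   monthly maxima, 2000–2018), sampled by inverse CDF.
2. **Rainfall** — the fitted linear model
   $312.692 - 7.83 \times \mathrm{maxtemp}$ mm plus
   $\mathrm{Uniform}(-75, 75)$ mm errors, clipped at 0 mm. The residual
   bounds of the original real-data regression are not published; ±75 mm is
   of the order of the published rainfall SD (51.69 mm). Clipping at zero is
   a physical constraint (a flag disables it).
3. **Fire counts** — two modes:
   * `residual_uniform` (default, the study's construction): the
     deterministic NB mean $\exp(\eta_t)$ plus bounded uniform count-scale
     residuals, rounded half away from zero and clamped at 0. The residual
     bounds are likewise unpublished; the default ±50 counts reproduces the
     scale of the published simulated-data NB training error. In this mode
     the dispersion grid value $\theta$ never enters generation, so metric
     rows are identical across $\theta$ at a fixed seed — exactly the
     near-duplicate rows the original study tabulates.
   * `nb_sample`: genuine $\mathrm{NB}(\mu_t, \theta)$ draws, added so that
     dispersion-sensitive properties (parameter recovery, the variance
     identity $\mu + \mu^2/\theta$) are testable.

   The default coefficient vector (7.69, 0.002, −0.09, 0.83, −0.05) is the
   published Bayesian fit to the real series — the count model actually
   fitted to the real data is not published, and the Bayesian point
   estimates are the closest printed object.

Seeding: a master seed (default 76568) plus `(n, replicate_id)` determine a
31-bit per-replicate seed; $\theta$ is deliberately excluded from the
derivation (see above). Determinism is promised within this implementation,
not across RNG implementations.

What the generator does **not** emulate: autocorrelated climate (months are
iid), long-term trends and era effects, outliers, zero-inflation, and any
spatial structure. Passing simulation tests therefore demonstrate estimator
correctness under the stated stochastic structure, not forecasting skill on
real fire regimes.

## Evaluation harness

Series are split sequentially (first `floor(0.8 n)` months train, remainder
test; no shuffling). Metrics:

* **RMSE** on train and test;
* **MASE** with the non-seasonal one-step in-sample naive scaling — test MAE
  divided by the training mean of $|y_t - y_{t-1}|$ (the convention of the
  widely used error-metric implementations);
* **percent bias** $100 \cdot \mathrm{mean}((y - \hat y)/y)$, negative when
  over-predicting; zero actuals raise an error by default (an explicit
  epsilon offset is available behind a flag);
* 90% central prediction intervals — plug-in NB quantiles for the ML fit
  (estimation uncertainty ignored, documented as approximate) and pooled
  posterior-predictive quantiles for the Bayesian fit — plus empirical
  coverage and the observed-vs-predicted Pearson correlation $t$ test.

For the Bayesian arm the prediction entering the metrics is, by default, a
*single posterior-predictive draw* (the original study's stated convention),
selectable to the posterior mean via `bnb_prediction = "posterior_mean"`.
Note the consequence: a single predictive draw carries the full predictive
noise, so under this convention the Bayesian arm's MASE/RMSE are inflated
relative to the ML arm's mean predictions on identically generated data.

Scenario averages are arithmetic means over replicates; per-replicate records
are retained so medians can be recomputed. Replicate-level fit failures are
excluded and counted, never silent; an arm losing more than 20% of its
replicates aborts the study.

## Problem sizes

The test suite and the bundled acceptance script are sized for a desk run:
parameter recovery and Bayesian/ML agreement at $n = 5000$ with two short
chains, interval calibration on 2000 points, the full 16-scenario grid at
one replicate for the harness contracts, and the $\theta = 1.5, n = 60$
scenario at 200 replicates (short chains) for the headline metrics. The full
published design — 1000 replicates per scenario with 4 × 2000-iteration
chains — runs through the same code paths via `cmd_study()`.

## Known limitations

* The frequentist prediction intervals are plug-in; they under-cover
  slightly when the training series is short.
* In `residual_uniform` mode the fitted dispersion is essentially
  unidentified (see above); interpret $\hat\phi$ there as "large".
* Percent bias explodes when test-segment actuals are small; the seasonal
  trough months dominate the scenario averages.
* The aggregation stage deliberately stops at country-month aggregates: no
  raster intersection, reprojection or download tooling.
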