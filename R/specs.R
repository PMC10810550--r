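#' Truncated-normal specification for monthly maximum temperature
#'
#' Defines the distribution used to generate the maximum-temperature covariate:
#' a normal distribution with mean `mu` and standard deviation `sigma`,
#' conditioned on the interval `[lower, upper]`. The defaults are the moments
#' and bounds of Kenyan monthly maximum temperature (degrees Celsius) over
#' 2000-2018.
#'
#' @param mu Mean of the untruncated normal, degrees C.
#' @param sigma Standard deviation of the untruncated normal, degrees C;
#'   must be positive.
#' @param lower,upper Truncation bounds, degrees C; `lower < upper`.
#'
#' @return An object of class `trunc_normal_spec`.
#' @export
#' @examples
#' trunc_normal_spec()
trunc_normal_spec <- function(mu = 29.18, sigma = 2.29,
                              lower = 23.43, upper = 34.82) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    stop("`lower` must be strictly below `upper`", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, lower = lower, upper = upper),
            class = "trunc_normal_spec")
}

#' Linear rainfall model specification
#'
#' Rainfall (mm) is generated as a linear function of maximum temperature plus
#' a bounded uniform error: `rainfall = intercept + slope * max_temp + u`,
#' `u ~ Uniform(error_low, error_high)`. The default intercept and slope are
#' the coefficients of the simple linear regression of monthly rainfall on
#' maximum temperature fitted to the real Kenyan series. Negative values are
#' clipped at zero by default (rainfall is physically nonnegative).
#'
#' @param intercept Intercept, mm.
#' @param slope Slope, mm per degree C.
#' @param error_low,error_high Uniform error bounds, mm; `error_low <=
#'   error_high`. The default half-width (75 mm) is of the order of the
#'   rainfall standard deviation in the real data (51.69 mm).
#' @param floor_at_zero If `TRUE` (default) clip simulated rainfall at 0 mm.
#'
#' @return An object of class `rainfall_spec`.
#' @export
rainfall_spec <- function(intercept = 312.692, slope = -7.83,
                          error_low = -75, error_high = 75,
                          floor_at_zero = TRUE) {
  if (error_low > error_high) {
    stop("`error_low` must not exceed `error_high`", call. = FALSE)
  }
  structure(list(intercept = intercept, slope = slope,
                 error_low = error_low, error_high = error_high,
                 floor_at_zero = isTRUE(floor_at_zero)),
            class = "rainfall_spec")
}

#' Count-model specification for fire-count generation
#'
#' Monthly fire counts are generated from a log-link Negative Binomial mean:
#' `eta_t = coef . (1, rainfall_t, max_temp_t, sin(2 pi t / period),
#' cos(2 pi t / period))`. Two generation modes are supported:
#'
#' * `"residual_uniform"` (default): `count_t = max(0, round(exp(eta_t) +
#'   u_t))` with `u_t ~ Uniform(resid_low, resid_high)` — deterministic mean
#'   plus a bounded count-scale residual, mimicking a residual-resampling
#'   scheme. In this mode `theta` plays no role in generation.
#' * `"nb_sample"`: `count_t ~ NB(mean = exp(eta_t), dispersion = theta)` —
#'   a genuine Negative Binomial draw, so the dispersion grid is informative.
#'
#' The default coefficient vector is the Bayesian NB fit to the real Kenyan
#' series (intercept 7.69, rainfall 0.002, max temperature -0.09, sine 0.83,
#' cosine -0.05).
#'
#' @param coef Numeric 5-vector on the log-link scale, ordered (intercept,
#'   rainfall, max_temp, sine, cosine).
#' @param theta NB dispersion parameter, positive; variance is
#'   `mu + mu^2 / theta`.
#' @param period Months per seasonal cycle; at least 2. Default 12 (annual).
#' @param mode `"residual_uniform"` or `"nb_sample"`.
#' @param resid_low,resid_high Count-scale residual bounds for
#'   `"residual_uniform"` mode.
#'
#' @return An object of class `count_spec`.
#' @export
count_spec <- function(coef = c(7.69, 0.002, -0.09, 0.83, -0.05),
                       theta = 1.5, period = 12,
                       mode = c("residual_uniform", "nb_sample"),
                       resid_low = -50, resid_high = 50) {
  mode <- match.arg(mode)
  if (length(coef) != 5L || !is.numeric(coef)) {
    stop("`coef` must be a numeric 5-vector", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("`theta` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(period) || length(period) != 1L || period < 2) {
    stop("`period` must be >= 2", call. = FALSE)
  }
  if (resid_low > resid_high) {
    stop("`resid_low` must not exceed `resid_high`", call. = FALSE)
  }
  structure(list(coef = as.numeric(coef), theta = theta, period = period,
                 mode = mode, resid_low = resid_low, resid_high = resid_high),
            class = "count_spec")
}

#' Simulation scenario configuration
#'
#' One cell of the simulation-study design: a series length `n` (months), a
#' dispersion `theta`, the number of replicate datasets and the master seed
#' from which per-replicate random streams are derived.
#'
#' @param n Series length in months; positive.
#' @param theta NB dispersion for the scenario; positive.
#' @param n_replicates Number of replicate datasets; positive. The full study
#'   design used 1000.
#' @param master_seed Integer master seed (default 76568).
#'
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n, theta, n_replicates = 1000,
                            master_seed = 76568) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("`theta` must be positive", call. = FALSE)
  }
  if (!is.numeric(n_replicates) || n_replicates <= 0) {
    stop("`n_replicates` must be positive", call. = FALSE)
  }
  structure(list(n = as.integer(n), theta = theta,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed)),
            class = "scenario_config")
}

#' Cartesian scenario grid
#'
#' Builds the full simulation design as the Cartesian product of dispersion
#' values and series lengths, ordered theta-major (all lengths for the first
#' theta, then the next theta, ...). The default grid of 4 dispersions by 4
#' lengths gives the 16-scenario study design.
#'
#' @param thetas Nonempty numeric vector of dispersion values.
#' @param ns Nonempty numeric vector of series lengths (months).
#' @param n_replicates Replicates per scenario.
#' @param master_seed Integer master seed shared by all scenarios.
#'
#' @return A list of [scenario_config()] objects, length
#'   `length(thetas) * length(ns)`.
#' @export
#' @examples
#' length(scenario_grid())  # 16
scenario_grid <- function(thetas = c(1.5, 5, 10, 100),
                          ns = c(60, 120, 240, 360),
                          n_replicates = 1000, master_seed = 76568) {
  if (length(thetas) == 0L || length(ns) == 0L) {
    stop("`thetas` and `ns` must be nonempty", call. = FALSE)
  }
  out <- vector("list", length(thetas) * length(ns))
  k <- 0L
  for (th in thetas) {
    for (n in ns) {
      k <- k + 1L
      out[[k]] <- scenario_config(n = n, theta = th,
                                  n_replicates = n_replicates,
                                  master_seed = master_seed)
    }
  }
  out
}
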