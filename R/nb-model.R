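# Maximum-likelihood Negative Binomial regression with harmonic seasonality.

#' Harmonic seasonal pseudo-covariates
#'
#' Returns `sin(2 pi t / period)` and `cos(2 pi t / period)` for a time index,
#' the standard sine-cosine parameterisation of a smooth seasonal cycle
#' (period 12 for monthly data with annual seasonality).
#'
#' @param time Integer (or numeric) time index.
#' @param period Months per cycle, at least 2.
#' @return A list with components `sin_term` and `cos_term`.
#' @export
#' @examples
#' harmonic_features(1:12)
harmonic_features <- function(time, period = 12) {
  if (period < 2) stop("`period` must be >= 2", call. = FALSE)
  w <- 2 * pi * time / period
  list(sin_term = sin(w), cos_term = cos(w))
}

#' Assemble model data with harmonic terms
#'
#' Validates a monthly series (`time`, `max_temp`, `rainfall`, `fire_count`)
#' and appends the harmonic columns `sin_term`, `cos_term`. All model-fitting
#' and prediction functions accept either a raw series or the output of this
#' function.
#'
#' @param series A series `data.frame`. For prediction-only use `fire_count`
#'   may be absent.
#' @param period Seasonal period in months.
#' @return The series with `sin_term` and `cos_term` columns appended.
#' @export
model_data <- function(series, period = 12) {
  need <- c("time", "max_temp", "rainfall")
  missing <- setdiff(need, names(series))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if ("fire_count" %in% names(series)) {
    y <- series$fire_count
    if (any(y < 0) || any(y != round(y))) {
      stop("`fire_count` must be nonnegative integers", call. = FALSE)
    }
  }
  h <- harmonic_features(series$time, period)
  series$sin_term <- h$sin_term
  series$cos_term <- h$cos_term
  attr(series, "period") <- period
  series
}

# design matrix in the canonical coefficient order
design_matrix <- function(data) {
  cbind(`(Intercept)` = 1, rainfall = data$rainfall, max_temp = data$max_temp,
        sin_term = data$sin_term, cos_term = data$cos_term)
}

nb_coef_names <- c("(Intercept)", "rainfall", "max_temp",
                   "sin_term", "cos_term")

#' Negative Binomial log probability mass
#'
#' Log pmf of the gamma-Poisson (Negative Binomial) distribution with mean
#' `mu` and dispersion `phi` (variance `mu + mu^2 / phi`), computed with
#' log-gamma terms so large counts do not overflow:
#' `lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) + y log(mu / (mu + phi)) +
#' phi log(phi / (mu + phi))`.
#'
#' @param y Nonnegative integer count(s).
#' @param mu Mean(s), positive.
#' @param phi Dispersion, positive; the Poisson limit is `phi -> Inf`.
#' @return Log probability, vectorised over the inputs.
#' @export
#' @examples
#' nb_log_pmf(0, 1, 1)  # log(1/2)
nb_log_pmf <- function(y, mu, phi) {
  if (any(y < 0) || any(y != round(y))) {
    stop("`y` must be nonnegative integers", call. = FALSE)
  }
  if (any(mu <= 0) || any(phi <= 0)) {
    stop("`mu` and `phi` must be positive", call. = FALSE)
  }
  lgamma(y + phi) - lgamma(phi) - lgamma(y + 1) +
    y * (log(mu) - log(mu + phi)) + phi * (log(phi) - log(mu + phi))
}

#' Negative Binomial regression log-likelihood
#'
#' Sum of [nb_log_pmf()] over the rows of a model data set, with mean
#' `exp(X beta)` under the canonical coefficient order (intercept, rainfall,
#' max_temp, sin_term, cos_term).
#'
#' @param beta Numeric 5-vector of log-link coefficients.
#' @param phi Dispersion, positive.
#' @param data A series or [model_data()] frame with a `fire_count` column.
#' @return The log-likelihood value.
#' @export
nb_loglik <- function(beta, phi, data) {
  if (is.null(data$sin_term)) data <- model_data(data)
  eta <- drop(design_matrix(data) %*% beta)
  if (any(!is.finite(eta))) {
    stop("nonfinite linear predictor in nb_loglik", call. = FALSE)
  }
  sum(nb_log_pmf(data$fire_count, exp(eta), phi))
}

#' Fit the Negative Binomial regression by maximum likelihood
#'
#' Fits `fire_count ~ rainfall + max_temp + sin_term + cos_term` with a log
#' link and a freely estimated dispersion, via [MASS::glm.nb()]. If that
#' fails (e.g. near-degenerate dispersion), a direct optimisation of
#' [nb_loglik()] over `(beta, log phi)` is used instead.
#'
#' @param data A series or [model_data()] frame.
#' @param period Seasonal period used if harmonic columns are absent.
#' @return An object of class `nb_fit` with components `beta` (named
#'   5-vector), `phi`, `se` (6 entries, coefficients plus `phi`), `vcov`,
#'   `loglik`, `converged`, `message`, and the training frame.
#' @export
fit_nb <- function(data, period = 12) {
  if (is.null(data$sin_term)) data <- model_data(data, period)
  n <- nrow(data)
  if (n <= 5L) stop("need more rows than parameters to fit", call. = FALSE)
  if (all(data$fire_count == 0)) {
    stop("all counts are zero; NB fit is degenerate", call. = FALSE)
  }
  msg <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      MASS::glm.nb(fire_count ~ rainfall + max_temp + sin_term + cos_term,
                   data = data),
      error = function(e) e
    ),
    warning = function(w) {
      msg <<- c(msg, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (!inherits(fit, "error")) {
    beta_raw <- coef(fit)[nb_coef_names]
    names(beta_raw) <- nb_coef_names
    aliased <- is.na(beta_raw)
    if (any(aliased)) {
      msg <- c(msg, paste("aliased (constant) term(s) dropped:",
                          paste(nb_coef_names[aliased], collapse = ", ")))
    }
    # aliased terms contribute nothing on this design: coefficient 0, se NA
    vc_full <- matrix(NA_real_, 5, 5,
                      dimnames = list(nb_coef_names, nb_coef_names))
    vc <- vcov(fit)
    present <- intersect(rownames(vc), nb_coef_names[!aliased])
    vc_full[present, present] <- vc[present, present]
    phi <- fit$theta
    se <- c(sqrt(diag(vc_full)), phi = fit$SE.theta)
    out <- structure(list(
      beta = setNames(ifelse(aliased, 0, as.numeric(beta_raw)),
                      nb_coef_names),
      phi = as.numeric(phi),
      se = se,
      vcov = vc_full,
      loglik = as.numeric(logLik(fit)),
      converged = isTRUE(fit$converged),
      message = if (length(msg)) paste(unique(msg), collapse = "; ") else "",
      data = data,
      period = attr(data, "period") %||% period,
      engine = "glm.nb"
    ), class = "nb_fit")
    return(out)
  }
  # fallback: direct ML on (beta, log phi) starting from a Poisson-scale guess
  msg <- c(msg, paste("glm.nb failed:", conditionMessage(fit)))
  start <- c(log(mean(data$fire_count) + 0.5), 0, 0, 0, 0, 0)
  negll <- function(par) -nb_loglik(par[1:5], exp(par[6]), data)
  opt <- optim(start, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500))
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 6, 6)
  })
  se6 <- sqrt(pmax(diag(vc), 0))
  phi <- exp(opt$par[6])
  structure(list(
    beta = setNames(opt$par[1:5], nb_coef_names),
    phi = phi,
    se = setNames(c(se6[1:5], phi * se6[6]), c(nb_coef_names, "phi")),
    vcov = vc[1:5, 1:5],
    loglik = -opt$value,
    converged = opt$convergence == 0,
    message = paste(unique(msg), collapse = "; "),
    data = data,
    period = attr(data, "period") %||% period,
    engine = "optim"
  ), class = "nb_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative Binomial regression (log link, maximum likelihood)\n")
  cat(sprintf("  n = %d, dispersion phi = %.4g, logLik = %.3f%s\n",
              nrow(x$data), x$phi, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$beta, se = x$se[seq_len(5)])
  print(round(tab, 4))
  invisible(x)
}

#' Coefficient summary table
#'
#' Returns a `term, estimate, se, ci_lower, ci_upper` table (Wald 95%
#' intervals for the ML fit; posterior central 95% credible intervals for the
#' Bayesian fit), the layout used for reporting fitted coefficients.
#'
#' @param fit An `nb_fit` or `bnb_fit`.
#' @param level Interval probability, default 0.95.
#' @return A `data.frame` with one row per coefficient plus the dispersion.
#' @export
coef_table <- function(fit, level = 0.95) UseMethod("coef_table")

#' @export
coef_table.nb_fit <- function(fit, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  est <- c(fit$beta, phi = fit$phi)
  se <- fit$se
  data.frame(term = names(est), estimate = as.numeric(est),
             se = as.numeric(se),
             ci_lower = as.numeric(est - z * se),
             ci_upper = as.numeric(est + z * se),
             row.names = NULL)
}
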