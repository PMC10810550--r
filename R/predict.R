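# Point predictions, posterior-predictive draws and prediction intervals.

#' Predicted mean fire counts
#'
#' For an ML fit, `exp(X beta_hat)`. For a Bayesian fit, the per-row average
#' of `exp(X alpha)` over the posterior draws (the posterior expectation of
#' the NB mean).
#'
#' @param fit An `nb_fit` or `bnb_fit`.
#' @param newdata A series or [model_data()] frame; `fire_count` not needed.
#' @return Numeric vector of predicted means, one per row of `newdata`.
#' @export
predict_mean <- function(fit, newdata) UseMethod("predict_mean")

#' @export
predict_mean.nb_fit <- function(fit, newdata) {
  if (is.null(newdata$sin_term)) newdata <- model_data(newdata, fit$period)
  drop(exp(design_matrix(newdata) %*% fit$beta))
}

#' @export
predict_mean.bnb_fit <- function(fit, newdata) {
  if (is.null(newdata$sin_term)) newdata <- model_data(newdata, fit$period)
  A <- draw_matrix(fit)[, 1:5, drop = FALSE]
  eta <- design_matrix(newdata) %*% t(A)  # rows x draws
  rowMeans(exp(eta))
}

#' Posterior-predictive count draws
#'
#' `mode = "single_draw"` selects one posterior draw uniformly at random and
#' generates one NB count per row from it — the convention used when a single
#' predictive realisation stands in for "the model's prediction" in
#' performance evaluation. `mode = "per_draw"` returns the full predictive
#' matrix (one row per posterior draw, one column per observation).
#'
#' @param fit A `bnb_fit` with at least one posterior draw.
#' @param newdata A series or [model_data()] frame.
#' @param mode `"single_draw"` or `"per_draw"`.
#' @return `single_draw`: integer vector of length `nrow(newdata)`;
#'   `per_draw`: an `ndraws x nrow(newdata)` matrix.
#' @export
posterior_predictive_draw <- function(fit, newdata,
                                      mode = c("single_draw", "per_draw")) {
  stopifnot(inherits(fit, "bnb_fit"))
  mode <- match.arg(mode)
  A <- draw_matrix(fit)
  if (nrow(A) < 1L) stop("posterior contains no draws", call. = FALSE)
  if (is.null(newdata$sin_term)) newdata <- model_data(newdata, fit$period)
  X <- design_matrix(newdata)
  n <- nrow(X)
  if (mode == "single_draw") {
    k <- sample.int(nrow(A), 1)
    mu <- drop(exp(X %*% A[k, 1:5]))
    rnbinom(n, size = A[k, 6], mu = mu)
  } else {
    mu <- exp(X %*% t(A[, 1:5, drop = FALSE]))  # n x ndraws
    nd <- nrow(A)
    out <- matrix(rnbinom(n * nd, size = rep(A[, 6], each = n), mu = mu),
                  nrow = n)
    t(out)  # ndraws x n
  }
}

#' Central prediction intervals for fire counts
#'
#' For the ML fit, plug-in NB quantiles at `(1 - level)/2` and
#' `1 - (1 - level)/2` using the fitted `(mu, phi)` (estimation uncertainty
#' ignored; the intervals are approximate). For the Bayesian fit, the same
#' quantiles of the pooled posterior-predictive draws, which propagate
#' parameter uncertainty.
#'
#' @param fit An `nb_fit` or `bnb_fit`.
#' @param newdata A series or [model_data()] frame.
#' @param level Central interval probability in (0, 1); default 0.9.
#' @return A `data.frame` of class `prediction_set` with columns `mean`,
#'   `lower`, `upper` and attribute `level`.
#' @export
prediction_interval <- function(fit, newdata, level = 0.9) {
  UseMethod("prediction_interval")
}

check_level <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("`level` must be a single probability in (0, 1)", call. = FALSE)
  }
}

#' @export
prediction_interval.nb_fit <- function(fit, newdata, level = 0.9) {
  check_level(level)
  mu <- predict_mean(fit, newdata)
  a <- (1 - level) / 2
  out <- data.frame(mean = mu,
                    lower = qnbinom(a, size = fit$phi, mu = mu),
                    upper = qnbinom(1 - a, size = fit$phi, mu = mu))
  structure(out, level = level, class = c("prediction_set", "data.frame"))
}

#' @export
prediction_interval.bnb_fit <- function(fit, newdata, level = 0.9) {
  check_level(level)
  draws <- posterior_predictive_draw(fit, newdata, mode = "per_draw")
  a <- (1 - level) / 2
  out <- data.frame(mean = predict_mean(fit, newdata),
                    lower = apply(draws, 2, quantile, probs = a),
                    upper = apply(draws, 2, quantile, probs = 1 - a))
  structure(out, level = level, class = c("prediction_set", "data.frame"))
}
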