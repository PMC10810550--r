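# Sequential splitting and forecast metrics.

#' Sequential train/test split
#'
#' Time-ordered partition: the first `floor(ratio * n)` rows form the training
#' set, the remainder the test set. No shuffling — the split respects the
#' temporal order of the series.
#'
#' @param series A `data.frame` (or any object with rows) in temporal order.
#' @param ratio Training fraction in (0, 1); default 0.8.
#' @return A list with components `train`, `test` and `ratio`.
#' @export
#' @examples
#' sp <- sequential_split(data.frame(x = 1:60))
#' nrow(sp$train)  # 48
sequential_split <- function(series, ratio = 0.8) {
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  n <- nrow(series)
  if (is.null(n) || n < 5L) stop("series too short to split", call. = FALSE)
  k <- floor(ratio * n)
  if (k < 1L || k >= n) stop("degenerate split", call. = FALSE)
  list(train = series[seq_len(k), , drop = FALSE],
       test = series[(k + 1L):n, , drop = FALSE],
       ratio = ratio)
}

#' Root mean square error
#'
#' @param actual,predicted Aligned numeric vectors.
#' @return `sqrt(mean((actual - predicted)^2))`.
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 1L) {
    stop("`actual` and `predicted` must be nonempty and aligned",
         call. = FALSE)
  }
  sqrt(mean((actual - predicted)^2))
}

#' Mean absolute scaled error
#'
#' Forecast MAE scaled by the in-sample one-step naive MAE of the training
#' series: `mean(|actual - predicted|) / mean(|y_t - y_{t-1}|)` over the
#' training observations (non-seasonal scaling). Values below 1 beat the
#' naive forecast.
#'
#' @param actual_test,predicted_test Aligned test-segment vectors.
#' @param actual_train Training-segment actuals (length at least 2).
#' @return The MASE value.
#' @export
mase <- function(actual_test, predicted_test, actual_train) {
  if (length(actual_test) != length(predicted_test)) {
    stop("test vectors must be aligned", call. = FALSE)
  }
  if (length(actual_train) < 2L) {
    stop("`actual_train` needs at least 2 observations", call. = FALSE)
  }
  scale <- mean(abs(diff(actual_train)))
  if (scale == 0) {
    stop("constant training series: naive scaling denominator is zero",
         call. = FALSE)
  }
  mean(abs(actual_test - predicted_test)) / scale
}

#' Percent bias
#'
#' `100 * mean((actual - predicted) / actual)`. Negative values mean the
#' model over-predicts on average.
#'
#' @param actual,predicted Aligned vectors; `actual` must be nonzero unless
#'   `zero_offset` is supplied.
#' @param zero_offset Optional small constant added to `actual` in the
#'   denominator to tolerate zero actuals; by default zeros are an error.
#' @return Percent bias (percentage points).
#' @export
percent_bias <- function(actual, predicted, zero_offset = NULL) {
  if (length(actual) != length(predicted)) {
    stop("`actual` and `predicted` must be aligned", call. = FALSE)
  }
  denom <- actual
  if (is.null(zero_offset)) {
    if (any(actual == 0)) {
      stop("zero values in `actual`; percent bias undefined ",
           "(supply `zero_offset` to engage the epsilon policy)",
           call. = FALSE)
    }
  } else {
    denom <- actual + zero_offset
  }
  100 * mean((actual - predicted) / denom)
}

#' Empirical prediction-interval coverage
#'
#' Fraction of actual values falling inside `[lower, upper]` of a
#' [prediction_interval()] result.
#'
#' @param actual Numeric vector of observed values.
#' @param prediction_set A `prediction_set` (or any frame with `lower` and
#'   `upper` columns) aligned with `actual`.
#' @return Coverage fraction in `[0, 1]`.
#' @export
interval_coverage <- function(actual, prediction_set) {
  if (length(actual) != nrow(prediction_set)) {
    stop("`actual` and `prediction_set` must be aligned", call. = FALSE)
  }
  mean(actual >= prediction_set$lower & actual <= prediction_set$upper)
}

#' Observed-versus-predicted correlation test
#'
#' Pearson correlation with the classical t test:
#' `t = r * sqrt(df / (1 - r^2))`, `df = n - 2`, two-sided p-value.
#'
#' @param actual,predicted Aligned vectors, at least 3 pairs, both with
#'   nonzero variance.
#' @return An object of class `correlation_test` with components `r`, `t`,
#'   `df`, `p`.
#' @export
correlation_test <- function(actual, predicted) {
  if (length(actual) != length(predicted) || length(actual) < 3L) {
    stop("need at least 3 aligned pairs", call. = FALSE)
  }
  if (sd(actual) == 0 || sd(predicted) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(actual, predicted, method = "pearson")
  structure(list(r = unname(ct$estimate), t = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, t(%d) = %.3f, p = %.4g\n",
              x$r, x$df, x$t, x$p))
  invisible(x)
}
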