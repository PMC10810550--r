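# point predictions, posterior-predictive draws, prediction intervals

test_that("predict_mean matches the closed form for the ML fit", {
  f <- fit_nb(make_series(n = 60))
  # all-zero covariate row with beta = (log 5, 0, 0, 0, 0)
  f0 <- f
  f0$beta <- setNames(c(log(5), 0, 0, 0, 0), names(f$beta))
  row0 <- data.frame(time = 12, max_temp = 0, rainfall = 0)
  expect_equal(predict_mean(f0, row0), 5, tolerance = 1e-12)
  # monotone in a covariate with positive coefficient
  fpos <- f
  fpos$beta <- setNames(c(1, 0.1, 0, 0, 0), names(f$beta))
  lo <- data.frame(time = 12, max_temp = 25, rainfall = 10)
  hi <- data.frame(time = 12, max_temp = 25, rainfall = 20)
  expect_gt(predict_mean(fpos, hi), predict_mean(fpos, lo))
})

test_that("posterior mean prediction equals the draw-matrix average", {
  s <- make_series(n = 60)
  fb <- suppressWarnings(fit_bnb(s, chains = 2, warmup = 300, iter = 200,
                                 seed = 6))
  newdata <- s[1:5, ]
  p <- predict_mean(fb, newdata)
  # brute force over the stored draws
  A <- as.matrix(fb$draws[paste0("alpha", 0:4)])
  d <- model_data(newdata)
  X <- cbind(1, d$rainfall, d$max_temp, d$sin_term, d$cos_term)
  oracle <- rowMeans(exp(X %*% t(A)))
  expect_equal(p, oracle, tolerance = 1e-10)
})

test_that("posterior predictive draws have the right shape and determinism", {
  s <- make_series(n = 60)
  fb <- suppressWarnings(fit_bnb(s, chains = 2, warmup = 300, iter = 200,
                                 seed = 7))
  newdata <- s[1:10, ]
  set.seed(1)
  d1 <- posterior_predictive_draw(fb, newdata, "single_draw")
  expect_length(d1, 10)
  expect_true(all(d1 >= 0))
  set.seed(1)
  expect_identical(posterior_predictive_draw(fb, newdata, "single_draw"), d1)
  m <- posterior_predictive_draw(fb, newdata, "per_draw")
  expect_equal(dim(m), c(400, 10))
  # law of total expectation: per-draw column means track predict_mean
  pm <- predict_mean(fb, newdata)
  expect_lt(max(abs(colMeans(m) - pm) / pm), 0.2)
})

test_that("prediction intervals are central quantile intervals", {
  f <- fit_nb(make_series(n = 120))
  newdata <- make_series(n = 120)[1:20, ]
  pi90 <- prediction_interval(f, newdata, 0.9)
  expect_s3_class(pi90, "prediction_set")
  expect_equal(attr(pi90, "level"), 0.9)
  mu <- predict_mean(f, newdata)
  expect_equal(pi90$lower, qnbinom(0.05, size = f$phi, mu = mu))
  expect_equal(pi90$upper, qnbinom(0.95, size = f$phi, mu = mu))
  # nesting
  pi95 <- prediction_interval(f, newdata, 0.95)
  expect_true(all(pi95$lower <= pi90$lower))
  expect_true(all(pi95$upper >= pi90$upper))
  expect_error(prediction_interval(f, newdata, 1.2), "probability")
})

test_that("Bayesian intervals pool the posterior-predictive draws", {
  s <- make_series(n = 60)
  fb <- suppressWarnings(fit_bnb(s, chains = 2, warmup = 300, iter = 200,
                                 seed = 8))
  newdata <- s[1:5, ]
  set.seed(2)
  pi90 <- prediction_interval(fb, newdata, 0.9)
  expect_true(all(pi90$lower <= pi90$upper))
  expect_true(all(pi90$lower <= pi90$mean & pi90$mean <= pi90$upper))
})
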