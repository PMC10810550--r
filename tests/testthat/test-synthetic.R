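# synthetic monthly climate / fire-count generator

test_that("spec constructors validate their invariants", {
  expect_error(trunc_normal_spec(sigma = -1), "sigma")
  expect_error(trunc_normal_spec(lower = 30, upper = 25), "lower")
  expect_error(rainfall_spec(error_low = 10, error_high = -10), "error_low")
  expect_error(count_spec(theta = 0), "theta")
  expect_error(count_spec(coef = 1:3), "5-vector")
  expect_error(count_spec(resid_low = 5, resid_high = -5), "resid_low")
  expect_error(scenario_config(n = 0, theta = 1.5), "n")
  expect_error(scenario_grid(thetas = numeric(0)), "nonempty")
})

test_that("truncated-normal samples respect the bounds", {
  spec <- trunc_normal_spec()
  set.seed(42)
  x <- sample_max_temperature(1e5, spec)
  expect_length(x, 1e5)
  expect_gte(min(x), 23.43)
  expect_lte(max(x), 34.82)
})

test_that("degenerate sigma collapses the sample onto the mean", {
  spec <- trunc_normal_spec(sigma = 1e-9)
  set.seed(1)
  x <- sample_max_temperature(100, spec)
  expect_true(all(abs(x - 29.18) < 1e-6))
})

test_that("truncated-normal sampler agrees with a rejection-sampling oracle", {
  spec <- trunc_normal_spec()
  # oracle: sample the untruncated normal, keep values inside the bounds
  set.seed(7)
  raw <- rnorm(4e5, spec$mu, spec$sigma)
  oracle <- raw[raw >= spec$lower & raw <= spec$upper][1:1e5]
  set.seed(8)
  x <- sample_max_temperature(1e5, spec)
  # closed-form truncated-normal mean
  a <- (spec$lower - spec$mu) / spec$sigma
  b <- (spec$upper - spec$mu) / spec$sigma
  tn_mean <- spec$mu + spec$sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  mc_se <- sd(oracle) / sqrt(length(oracle))
  expect_lt(abs(mean(x) - tn_mean), 3 * mc_se)
  expect_lt(abs(mean(oracle) - tn_mean), 3 * mc_se)
  ks <- suppressWarnings(stats::ks.test(x, oracle))
  expect_gt(ks$p.value, 0.001)
})

test_that("rainfall follows the fitted linear model exactly when noiseless", {
  spec <- rainfall_spec(error_low = 0, error_high = 0)
  expect_equal(simulate_rainfall(29.18, spec), 84.2126, tolerance = 1e-8)
  flat <- rainfall_spec(slope = 0, error_low = 0, error_high = 0)
  expect_equal(simulate_rainfall(c(25, 30, 34), flat), rep(312.692, 3))
})

test_that("rainfall errors are uniform on the stated bounds", {
  spec <- rainfall_spec(floor_at_zero = FALSE)
  set.seed(3)
  temp <- sample_max_temperature(1e5)
  rain <- simulate_rainfall(temp, spec)
  err <- rain - (spec$intercept + spec$slope * temp)
  expect_gte(min(err), -75)
  expect_lte(max(err), 75)
  set.seed(4)
  oracle <- runif(1e5, -75, 75)
  ks <- suppressWarnings(stats::ks.test(err, oracle))
  expect_gt(ks$p.value, 0.001)
})

test_that("zero-noise residual_uniform counts equal the rounded NB mean", {
  spec <- count_spec(resid_low = 0, resid_high = 0)
  temp <- c(26, 29, 32)
  rain <- c(120, 80, 40)
  t <- 1:3
  eta <- spec$coef[1] + spec$coef[2] * rain + spec$coef[3] * temp +
    spec$coef[4] * sin(2 * pi * t / 12) + spec$coef[5] * cos(2 * pi * t / 12)
  y <- simulate_fire_counts(temp, rain, spec, time = t)
  expect_identical(y, as.integer(round(exp(eta))))
  # deterministic: same answer without touching the RNG state
  expect_identical(simulate_fire_counts(temp, rain, spec, time = t), y)
})

test_that("nb_sample counts satisfy the NB variance identity", {
  # constant eta with exp(eta) = 50: var = 50 + 50^2/1.5
  spec <- count_spec(coef = c(log(50), 0, 0, 0, 0), theta = 1.5,
                     mode = "nb_sample")
  set.seed(5)
  y <- simulate_fire_counts(rep(30, 1e5), rep(100, 1e5), spec)
  target <- 50 + 50^2 / 1.5
  # MC error of a sample variance: sd(var) ~ sqrt((kurt-1)/n) * var
  expect_equal(mean(y), 50, tolerance = 0.02)
  expect_lt(abs(var(y) - target) / target, 0.05)
})

test_that("count generation rejects overflowing linear predictors", {
  spec <- count_spec(coef = c(1000, 0, 0, 0, 0))
  expect_error(simulate_fire_counts(30, 100, spec), "overflow")
})

test_that("generate_series is deterministic and shaped correctly", {
  sc <- scenario_config(n = 60, theta = 1.5, n_replicates = 5)
  s1 <- generate_series(sc, 2)
  s2 <- generate_series(sc, 2)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 60L)
  expect_named(s1, c("time", "max_temp", "rainfall", "fire_count"))
  expect_true(all(s1$fire_count >= 0))
  expect_true(all(s1$fire_count == round(s1$fire_count)))
  expect_true(all(s1$max_temp >= 23.43 & s1$max_temp <= 34.82))
  # different replicates differ
  expect_false(identical(s1, generate_series(sc, 3)))
  expect_error(generate_series(sc, 6), "out of range")
})

test_that("default generator produces over-dispersed counts at realistic scale", {
  s <- make_series(n = 360)
  expect_gt(var(s$fire_count), mean(s$fire_count))
  expect_gt(mean(s$fire_count), 30)
  expect_lt(mean(s$fire_count), 3000)
})

test_that("scenario_grid enumerates the Cartesian product theta-major", {
  expect_length(scenario_grid(), 16)
  expect_length(scenario_grid(thetas = 1.5, ns = 60), 1)
  g <- scenario_grid(thetas = c(1.5, 5), ns = c(60, 120, 240))
  expect_length(g, 6)
  expect_equal(vapply(g, `[[`, 0, "theta"), c(1.5, 1.5, 1.5, 5, 5, 5))
  expect_equal(vapply(g, `[[`, 0L, "n"), rep(c(60L, 120L, 240L), 2))
})

test_that("series CSV round-trips", {
  s <- make_series(n = 60)
  f <- withr::local_tempfile(fileext = ".csv")
  write_series_csv(s, f)
  expect_equal(read_series_csv(f), s, tolerance = 1e-12)
  expect_error(read_series_csv(withr::local_tempfile(lines = "a,b\n1,2",
                                                     fileext = ".csv")),
               "missing columns")
})
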