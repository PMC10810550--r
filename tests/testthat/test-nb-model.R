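# NB pmf, likelihood and maximum-likelihood fitting

test_that("harmonic features obey the unit-circle identities", {
  h <- harmonic_features(12, 12)
  expect_equal(h$sin_term, 0, tolerance = 1e-12)
  expect_equal(h$cos_term, 1, tolerance = 1e-12)
  h3 <- harmonic_features(3, 12)
  expect_equal(h3$sin_term, 1, tolerance = 1e-12)
  expect_equal(h3$cos_term, 0, tolerance = 1e-12)
  t <- 1:100
  hh <- harmonic_features(t, 12)
  expect_equal(hh$sin_term^2 + hh$cos_term^2, rep(1, 100), tolerance = 1e-12)
  expect_equal(harmonic_features(t + 12, 12), hh, tolerance = 1e-12)
})

test_that("nb_log_pmf matches hand values and validates input", {
  expect_equal(nb_log_pmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  expect_error(nb_log_pmf(-1, 1, 1), "nonnegative")
  expect_error(nb_log_pmf(1.5, 1, 1), "nonnegative")
  expect_error(nb_log_pmf(1, -2, 1), "positive")
  # agrees with the canonical parameterisation in stats
  expect_equal(nb_log_pmf(7, 5, 1.5), dnbinom(7, size = 1.5, mu = 5,
                                              log = TRUE), tolerance = 1e-12)
})

test_that("nb pmf normalises over the support", {
  total <- sum(exp(nb_log_pmf(0:2000, 5, 1.5)))
  expect_lt(abs(total - 1), 1e-8)
})

test_that("nb_log_pmf approaches the Poisson limit as phi grows", {
  expect_lt(abs(nb_log_pmf(3, 2, 1e6) - dpois(3, 2, log = TRUE)), 1e-3)
})

test_that("nb_loglik is the row sum and is exchangeable", {
  d <- model_data(make_series(n = 10))
  beta <- c(7.5, 0.002, -0.09, 0.8, -0.05)
  # brute-force per-row oracle
  eta <- beta[1] + beta[2] * d$rainfall + beta[3] * d$max_temp +
    beta[4] * d$sin_term + beta[5] * d$cos_term
  oracle <- sum(vapply(seq_len(10), function(i) {
    nb_log_pmf(d$fire_count[i], exp(eta[i]), 2)
  }, 0))
  expect_equal(nb_loglik(beta, 2, d), oracle, tolerance = 1e-10)
  expect_equal(nb_loglik(beta, 2, d[sample(10), ]), oracle, tolerance = 1e-10)
  # single-row closed form: y = 0, all covariates 0, beta = 0, phi = 1
  row0 <- data.frame(time = 12, max_temp = 0, rainfall = 0, fire_count = 0)
  expect_equal(nb_loglik(rep(0, 5), 1, model_data(row0)), log(0.5),
               tolerance = 1e-9)
})

test_that("model_data validates counts and appends harmonics", {
  s <- make_series(n = 24)
  d <- model_data(s)
  expect_true(all(c("sin_term", "cos_term") %in% names(d)))
  s$fire_count[1] <- -1
  expect_error(model_data(s), "nonnegative")
  expect_error(model_data(data.frame(time = 1:5)), "missing columns")
})

test_that("fit_nb recovers an intercept-only mean", {
  set.seed(100)
  n <- 5000
  d <- data.frame(time = seq_len(n), max_temp = 0, rainfall = 0,
                  fire_count = rnbinom(n, size = 2, mu = 50))
  f <- fit_nb(d)
  expect_true(f$converged)
  mu_hat <- exp(f$beta[["(Intercept)"]])
  # delta method: se(exp(b0)) ~ exp(b0) * se(b0)
  expect_lt(abs(mu_hat - 50), 3 * mu_hat * f$se[["(Intercept)"]])
})

test_that("fit_nb recovers the full coefficient vector on nb_sample data", {
  truth <- c(7.69, 0.002, -0.09, 0.83, -0.05)
  cs <- count_spec(coef = truth, theta = 1.5, mode = "nb_sample")
  s <- generate_series(scenario_config(n = 5000, theta = 1.5,
                                       n_replicates = 1), 1, count = cs)
  f <- fit_nb(s)
  expect_true(f$converged)
  z <- abs(f$beta - truth) / f$se[1:5]
  expect_true(all(z < 3))
  # the fitted maximum beats the truth on its own objective
  expect_gte(nb_loglik(f$beta, f$phi, f$data),
             nb_loglik(truth, 1.5, f$data))
})

test_that("fit_nb rejects degenerate inputs", {
  tiny <- make_series(n = 60)[1:4, ]
  expect_error(fit_nb(tiny), "more rows")
  zeros <- make_series(n = 24)
  zeros$fire_count <- 0L
  expect_error(fit_nb(zeros), "zero")
})

test_that("coef_table emits the reporting layout", {
  f <- fit_nb(make_series(n = 60))
  tab <- coef_table(f)
  expect_named(tab, c("term", "estimate", "se", "ci_lower", "ci_upper"))
  expect_equal(nrow(tab), 6)  # 5 coefficients + dispersion
  expect_true(all(tab$ci_lower <= tab$estimate & tab$estimate <= tab$ci_upper))
})
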