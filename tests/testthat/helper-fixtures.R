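# shared fixtures built in code

# small default-parameter series for model tests
make_series <- function(n = 60, theta = 1.5, rep = 1, mode = "residual_uniform",
                        seed = 76568) {
  generate_series(
    scenario_config(n = n, theta = theta, n_replicates = max(10, rep),
                    master_seed = seed),
    rep,
    count = count_spec(theta = theta, mode = mode))
}

# hand-built FIRMS records: 3 vegetation fires + 2 other-static in Jan 2018,
# 1 vegetation fire in Feb 2018
make_firms_records <- function() {
  data.frame(
    latitude = c(0.5, -1.2, 2.0, 0.1, 3.3, -0.4),
    longitude = c(36.1, 37.0, 38.5, 35.2, 39.9, 36.6),
    brightness = c(320, 340, 310, 400, 355, 330),
    scan = 1.1, track = 1.0,
    acq_date = as.Date(c("2018-01-05", "2018-01-12", "2018-01-28",
                         "2018-01-15", "2018-01-20", "2018-02-03")),
    acq_time = "1030", satellite = "Terra", confidence = 80,
    version = "6.3", bright_t31 = 290,
    frp = c(10, 20, 30, 15, 25, 40),
    daynight = "D",
    type = c(0L, 0L, 0L, 2L, 2L, 0L)
  )
}

# monthly climate table covering 2018
make_climate_table <- function(years = 2018) {
  g <- expand.grid(month = 1:12, year = years)
  data.frame(year = g$year, month = g$month,
             rainfall = 80 + 10 * sin(2 * pi * g$month / 12),
             tmin = 17 + sin(2 * pi * g$month / 12),
             tmax = 29 + 2 * cos(2 * pi * g$month / 12))
}
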