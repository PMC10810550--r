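# FIRMS-style hotspot reading, monthly aggregation, climate join

write_records_csv <- function(records) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  d <- records
  d$acq_date <- format(d$acq_date, "%Y-%m-%d")
  write.csv(d, f, row.names = FALSE)
  f
}

test_that("read_firms_csv parses valid rows and counts invalid ones", {
  rec <- make_firms_records()
  f <- write_records_csv(rec)
  d <- read_firms_csv(f)
  expect_equal(nrow(d), 6)
  expect_s3_class(d$acq_date, "Date")
  expect_equal(attr(d, "n_excluded"), 0)

  bad <- rec
  bad$latitude[1] <- 95  # out of range
  f2 <- write_records_csv(bad)
  expect_message(d2 <- read_firms_csv(f2), "excluded 1")
  expect_equal(nrow(d2), 5)
  expect_equal(attr(d2, "n_excluded"), 1)
})

test_that("read_firms_csv names missing mandatory columns", {
  f <- withr::local_tempfile(lines = "latitude,longitude\n1,2",
                             fileext = ".csv")
  expect_error(read_firms_csv(f), "brightness")
})

test_that("concatenating files unions the records", {
  rec <- make_firms_records()
  f1 <- write_records_csv(rec[1:3, ])
  f2 <- write_records_csv(rec[4:6, ])
  both <- rbind(read_firms_csv(f1), read_firms_csv(f2))
  expect_equal(nrow(both), 6)
  f_all <- write_records_csv(rec)
  all_at_once <- read_firms_csv(f_all)
  attr(both, "n_excluded") <- NULL
  attr(all_at_once, "n_excluded") <- NULL
  rownames(both) <- NULL
  expect_equal(both, all_at_once)
})

test_that("monthly aggregation filters by type and conserves counts", {
  rec <- make_firms_records()
  m0 <- aggregate_monthly(rec)  # default: type 0 only
  expect_equal(m0$fire_count[m0$year == 2018 & m0$month == 1], 3)
  expect_equal(sum(m0$fire_count), sum(rec$type == 0))
  m_all <- aggregate_monthly(rec, types = NULL)
  expect_equal(m_all$fire_count[m_all$year == 2018 & m_all$month == 1], 5)
  expect_equal(sum(m_all$fire_count), nrow(rec))
  # filtering never increases a monthly count
  merged <- merge(m_all, m0, by = c("year", "month"), all.x = TRUE)
  merged$fire_count.y[is.na(merged$fire_count.y)] <- 0
  expect_true(all(merged$fire_count.y <= merged$fire_count.x))
  # mean features per month
  jan0 <- rec[rec$type == 0 & format(rec$acq_date, "%m") == "01", ]
  expect_equal(m0$mean_frp[m0$month == 1], mean(jan0$frp))
  expect_equal(m0$mean_brightness[m0$month == 1], mean(jan0$brightness))
  # months with no retained records are absent, not zero-filled
  expect_false(any(m0$month == 3))
})

test_that("aggregation is idempotent over its source records", {
  rec <- make_firms_records()
  expect_identical(aggregate_monthly(rec), aggregate_monthly(rec))
  expect_warning(empty <- aggregate_monthly(rec, types = 99), "no records")
  expect_equal(nrow(empty), 0)
})

test_that("merge_climate joins on year-month and indexes time", {
  rec <- make_firms_records()
  m <- aggregate_monthly(rec)
  clim <- make_climate_table()
  expect_warning(out <- merge_climate(m, clim), "fewer than 24")
  expect_named(out, c("time", "year", "month", "max_temp", "tmin",
                      "rainfall", "fire_count"))
  expect_equal(out$time, seq_len(nrow(out)))
  expect_equal(nrow(out), 2)  # Jan + Feb 2018
  expect_equal(out$max_temp, clim$tmax[clim$month %in% 1:2])
  # duplicate keys rejected
  expect_error(merge_climate(m, rbind(clim, clim[1, ])), "duplicate")
  # disjoint keys: empty join + warning
  clim2 <- make_climate_table(years = 1999)
  expect_warning(out2 <- merge_climate(m, clim2), "no rows")
  expect_equal(nrow(out2), 0)
})

test_that("fixture generator is deterministic with the requested type mix", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  make_firms_fixture(f1, n_records = 100, seed = 42)
  make_firms_fixture(f2, n_records = 100, seed = 42)
  expect_identical(readLines(f1), readLines(f2))
  d <- read_firms_csv(f1)
  expect_true(all(d$latitude >= -5 & d$latitude <= 5.5))
  expect_true(all(d$frp >= 0))
  # type mix at n = 1000 within binomial error of 80/10/10
  f3 <- withr::local_tempfile(fileext = ".csv")
  make_firms_fixture(f3, n_records = 1000, seed = 7)
  d3 <- read_firms_csv(f3)
  p0 <- mean(d3$type == 0)
  expect_lt(abs(p0 - 0.8), 3 * sqrt(0.8 * 0.2 / 1000))
  expect_lt(abs(mean(d3$type == 2) - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
})
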