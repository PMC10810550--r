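# FIRMS/MCD14DL-style active-fire hotspot CSVs: reading, monthly aggregation
# and joining to monthly climate.

firms_mandatory_cols <- c("latitude", "longitude", "brightness", "acq_date",
                          "frp", "type")

#' Read a FIRMS-style hotspot CSV
#'
#' Parses an MCD14DL-style CSV (columns `latitude, longitude, brightness,
#' scan, track, acq_date, acq_time, satellite, confidence, version,
#' bright_t31, frp, daynight, type`; extra columns are preserved untouched).
#' Rows with out-of-range coordinates (latitude outside \[-90, 90\], longitude
#' outside \[-180, 180\]), negative FRP or unparseable dates are excluded and
#' counted; the count is reported via a message and stored in the
#' `"n_excluded"` attribute.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` of valid records with `acq_date` parsed to `Date`,
#'   with attribute `n_excluded`.
#' @export
read_firms_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(firms_mandatory_cols, names(d))
  if (length(missing)) {
    stop("FIRMS CSV missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  date <- as.Date(as.character(d$acq_date), format = "%Y-%m-%d")
  ok <- !is.na(date) &
    is.finite(d$latitude) & d$latitude >= -90 & d$latitude <= 90 &
    is.finite(d$longitude) & d$longitude >= -180 & d$longitude <= 180 &
    is.finite(d$frp) & d$frp >= 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(sprintf("read_firms_csv: excluded %d malformed/invalid row(s)",
                    n_excluded))
  }
  d <- d[ok, , drop = FALSE]
  d$acq_date <- date[ok]
  rownames(d) <- NULL
  attr(d, "n_excluded") <- n_excluded
  d
}

#' Aggregate hotspot records to a monthly series
#'
#' Groups records by calendar `(year, month)` of the acquisition date,
#' keeping only the requested fire `type` codes (default 0, presumed
#' vegetation fire), and computes the monthly hotspot count plus mean FRP and
#' mean brightness. Months with no retained records are absent, not
#' zero-filled.
#'
#' @param records A `data.frame` from [read_firms_csv()] (or equivalent,
#'   with `acq_date` as `Date`, `frp`, `brightness`, `type`).
#' @param types Integer vector of type codes to keep; `NULL` keeps all.
#' @return A `data.frame` with columns `year, month, fire_count, mean_frp,
#'   mean_brightness`, ordered chronologically.
#' @export
aggregate_monthly <- function(records, types = 0L) {
  if (nrow(records) == 0L) stop("no records to aggregate", call. = FALSE)
  if (!is.null(types)) records <- records[records$type %in% types, ,
                                          drop = FALSE]
  if (nrow(records) == 0L) {
    warning("no records left after type filtering; returning empty series",
            call. = FALSE)
    return(data.frame(year = integer(), month = integer(),
                      fire_count = integer(), mean_frp = numeric(),
                      mean_brightness = numeric()))
  }
  year <- as.integer(format(records$acq_date, "%Y"))
  month <- as.integer(format(records$acq_date, "%m"))
  key <- data.frame(year = year, month = month)
  out <- aggregate(list(fire_count = rep(1L, nrow(records))), by = key, sum)
  means <- aggregate(list(mean_frp = records$frp,
                          mean_brightness = records$brightness),
                     by = key, mean)
  out <- merge(out, means, by = c("year", "month"))
  out <- out[order(out$year, out$month), ]
  rownames(out) <- NULL
  out
}

#' Join monthly fire counts to monthly climate
#'
#' Inner join on `(year, month)` producing the modelling table with a
#' chronological time index. The climate table must have columns
#' `year, month, rainfall, tmin, tmax` with unique `(year, month)` keys.
#'
#' @param fire_series Output of [aggregate_monthly()].
#' @param climate_table Monthly climate `data.frame`.
#' @return A `data.frame` with columns `time, year, month, max_temp, tmin,
#'   rainfall, fire_count`, `time = 1..n` in chronological order.
#' @export
merge_climate <- function(fire_series, climate_table) {
  need <- c("year", "month", "rainfall", "tmin", "tmax")
  missing <- setdiff(need, names(climate_table))
  if (length(missing)) {
    stop("climate table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (d in list(fire_series, climate_table)) {
    if (anyDuplicated(d[c("year", "month")])) {
      stop("duplicate (year, month) keys", call. = FALSE)
    }
  }
  m <- merge(fire_series, climate_table, by = c("year", "month"))
  m <- m[order(m$year, m$month), ]
  if (nrow(m) == 0L) {
    warning("join produced no rows (disjoint keys)", call. = FALSE)
  } else if (nrow(m) < 24L) {
    warning("join produced fewer than 24 months", call. = FALSE)
  }
  out <- data.frame(time = seq_len(nrow(m)), year = m$year, month = m$month,
                    max_temp = m$tmax, tmin = m$tmin, rainfall = m$rainfall,
                    fire_count = m$fire_count)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic FIRMS-style fixture CSV
#'
#' Writes a synthetic MCD14DL-format CSV with realistic field ranges
#' (Kenya-like coordinates: latitude in \[-5, 5.5\], longitude in
#' \[33.9, 41.9\]) and a configurable mix of fire type codes, deterministic
#' under the seed. Intended for tests and demonstrations of the aggregation
#' stage; the records are synthetic, not satellite detections.
#'
#' @param path Output CSV path.
#' @param n_records Number of records, at least 1.
#' @param date_range Length-2 `Date` (or parseable character) vector.
#' @param type_probs Named probabilities over type codes, e.g.
#'   `c("0" = 0.8, "2" = 0.1, "3" = 0.1)`.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
make_firms_fixture <- function(path, n_records = 100,
                               date_range = c("2018-01-01", "2018-12-31"),
                               type_probs = c("0" = 0.8, "2" = 0.1,
                                              "3" = 0.1),
                               seed = 1L) {
  stopifnot(n_records >= 1)
  date_range <- as.Date(date_range)
  codes <- as.integer(names(type_probs))
  withr::with_seed(seed, {
    days <- sample(seq(date_range[1], date_range[2], by = "day"),
                   n_records, replace = TRUE)
    d <- data.frame(
      latitude = round(runif(n_records, -5, 5.5), 4),
      longitude = round(runif(n_records, 33.9, 41.9), 4),
      brightness = round(runif(n_records, 300, 420), 1),
      scan = round(runif(n_records, 1, 4), 1),
      track = round(runif(n_records, 1, 2), 1),
      acq_date = format(days, "%Y-%m-%d"),
      acq_time = sprintf("%02d%02d", sample(0:23, n_records, TRUE),
                         sample(0:59, n_records, TRUE)),
      satellite = sample(c("Terra", "Aqua"), n_records, TRUE),
      confidence = sample(0:100, n_records, TRUE),
      version = "6.3",
      bright_t31 = round(runif(n_records, 270, 310), 1),
      frp = round(rgamma(n_records, shape = 2, rate = 0.08), 1),
      daynight = sample(c("D", "N"), n_records, TRUE),
      type = sample(codes, n_records, TRUE, prob = as.numeric(type_probs))
    )
  })
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
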