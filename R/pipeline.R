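# Pipeline commands: simulate, fit, study, aggregate. Thin orchestration over
# the generator, models, evaluation harness and hotspot aggregation, with
# plain-text configs and JSON run manifests.

#' Read a plain-text key-value configuration file
#'
#' Format: one `key = value` per line, `#` comments allowed. Comma-separated
#' values become vectors; numeric-looking values are converted to numeric.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("config line without '=': ", ln, call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) num else parts
  }
  out
}

cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

# build generator/prior specs from a config list, defaults where unset
specs_from_config <- function(cfg = list()) {
  list(
    tn = trunc_normal_spec(
      mu = cfg_get(cfg, "tn_mu", 29.18),
      sigma = cfg_get(cfg, "tn_sigma", 2.29),
      lower = cfg_get(cfg, "tn_lower", 23.43),
      upper = cfg_get(cfg, "tn_upper", 34.82)),
    rain = rainfall_spec(
      intercept = cfg_get(cfg, "rain_intercept", 312.692),
      slope = cfg_get(cfg, "rain_slope", -7.83),
      error_low = cfg_get(cfg, "rain_error_low", -75),
      error_high = cfg_get(cfg, "rain_error_high", 75),
      floor_at_zero = as.logical(cfg_get(cfg, "rain_floor_at_zero", TRUE))),
    count = count_spec(
      coef = cfg_get(cfg, "count_coef", c(7.69, 0.002, -0.09, 0.83, -0.05)),
      theta = cfg_get(cfg, "count_theta", 1.5),
      period = cfg_get(cfg, "period", 12),
      mode = cfg_get(cfg, "count_mode", "residual_uniform"),
      resid_low = cfg_get(cfg, "count_resid_low", -50),
      resid_high = cfg_get(cfg, "count_resid_high", 50)),
    priors = prior_spec(
      coef_prior_sd = cfg_get(cfg, "prior_coef_sd", 10),
      disp_shape = cfg_get(cfg, "prior_disp_shape", 0.01),
      disp_rate = cfg_get(cfg, "prior_disp_rate", 0.01))
  )
}

write_manifest <- function(out_dir, command, params, outputs) {
  manifest <- list(
    command = command,
    params = params,
    package_version = as.character(packageVersion("firenb")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate replicate datasets to CSV files
#'
#' Generates the scenario grid and writes one CSV per replicate, named
#' `sim_theta{theta}_n{n}_rep{r}.csv` inside a `theta{theta}_n{n}/` directory
#' per scenario, plus a JSON run manifest recording every parameter actually
#' used.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Optional path to a [read_config()] file; explicit arguments
#'   override config values.
#' @param thetas,ns Scenario grid axes.
#' @param reps Replicates per scenario.
#' @param seed Master seed.
#' @return Character vector of written series files, invisibly.
#' @export
cmd_simulate <- function(out_dir, config = NULL,
                         thetas = NULL, ns = NULL, reps = NULL, seed = NULL) {
  cfg <- if (!is.null(config)) read_config(config) else list()
  thetas <- thetas %||% cfg_get(cfg, "thetas", c(1.5, 5, 10, 100))
  ns <- ns %||% cfg_get(cfg, "ns", c(60, 120, 240, 360))
  reps <- reps %||% cfg_get(cfg, "reps", 10)
  seed <- seed %||% cfg_get(cfg, "seed", 76568)
  sp <- specs_from_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- scenario_grid(thetas, ns, n_replicates = reps, master_seed = seed)
  files <- character(0)
  for (sc in grid) {
    sub <- file.path(out_dir, sprintf("theta%g_n%d", sc$theta, sc$n))
    dir.create(sub, showWarnings = FALSE)
    for (r in seq_len(sc$n_replicates)) {
      s <- generate_series(sc, r, tn = sp$tn, rain = sp$rain, count = sp$count)
      f <- file.path(sub, sprintf("sim_theta%g_n%d_rep%d.csv",
                                  sc$theta, sc$n, r))
      write_series_csv(s, f)
      files <- c(files, f)
    }
  }
  write_manifest(out_dir, "simulate",
                 params = list(thetas = thetas, ns = ns, reps = reps,
                               seed = seed, tn = unclass(sp$tn),
                               rain = unclass(sp$rain),
                               count = unclass(sp$count)),
                 outputs = basename(files))
  invisible(files)
}

#' Fit a model to a series CSV and emit estimates, predictions and intervals
#'
#' Fits the requested model, writes `estimates.csv`
#' (`term,estimate,se,ci_lower,ci_upper`, plus an `rhat` column for the
#' Bayesian model), `predictions.csv` with 90% prediction intervals, and —
#' when `split` is given — test-segment `metrics.csv` (rmse, mase, bias).
#' A non-converged Bayesian fit (any split-Rhat above 1.01) aborts unless
#' `force = TRUE`.
#'
#' @param input Path to a series CSV (`time,max_temp,rainfall,fire_count`).
#' @param model `"nb"` or `"bnb"`.
#' @param out_dir Output directory.
#' @param split Optional training fraction; if given, the model is fitted on
#'   the training segment and predictions/metrics are for the test segment.
#' @param level Prediction-interval probability (default 0.9).
#' @param seed Seed for the Bayesian sampler and predictive draws.
#' @param chains,warmup,iter Sampler settings for `model = "bnb"`.
#' @param force Emit the Bayesian summary even when not converged.
#' @return The fitted model object, invisibly.
#' @export
cmd_fit <- function(input, model = c("nb", "bnb"), out_dir,
                    split = NULL, level = 0.9, seed = 1L,
                    chains = 4, warmup = 1000, iter = 1000, force = FALSE) {
  model <- match.arg(model)
  series <- read_series_csv(input)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(split)) {
    sp <- sequential_split(series, split)
    train <- sp$train; test <- sp$test
  } else {
    train <- series; test <- series
  }
  if (model == "nb") {
    fit <- fit_nb(train)
    est <- coef_table(fit)
    pred <- withr::with_seed(seed, prediction_interval(fit, test, level))
    p_test <- predict_mean(fit, test)
  } else {
    fit <- fit_bnb(train, chains = chains, warmup = warmup, iter = iter,
                   seed = seed)
    if (!fit$converged && !force) {
      stop("Bayesian fit did not converge (split-Rhat > 1.01); ",
           "rerun with more iterations or force = TRUE", call. = FALSE)
    }
    est <- coef_table(fit)
    est$rhat <- as.numeric(fit$rhat)
    pred <- withr::with_seed(seed + 1L, prediction_interval(fit, test, level))
    p_test <- withr::with_seed(seed + 2L,
                               posterior_predictive_draw(fit, test,
                                                         "single_draw"))
    write_draws_csv(fit, file.path(out_dir, "draws.csv"))
  }
  write.csv(est, file.path(out_dir, "estimates.csv"), row.names = FALSE)
  out_pred <- cbind(test["time"], as.data.frame(pred))
  write.csv(out_pred, file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  outputs <- c("estimates.csv", "predictions.csv")
  if (!is.null(split)) {
    metrics <- data.frame(
      metric = c("rmse", "mase", "bias_pct"),
      value = c(rmse(test$fire_count, p_test),
                mase(test$fire_count, p_test, train$fire_count),
                percent_bias(test$fire_count, p_test)))
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    outputs <- c(outputs, "metrics.csv")
  }
  write_manifest(out_dir, "fit",
                 params = list(input = input, model = model, split = split,
                               level = level, seed = seed, chains = chains,
                               warmup = warmup, iter = iter),
                 outputs = outputs)
  invisible(fit)
}

#' Run the full simulation study and emit summary tables
#'
#' Runs [run_simulation_study()] over the configured grid with per-scenario
#' checkpointing (an interrupted run resumes from the per-scenario replicate
#' CSVs under `checkpoints/`), then writes `table1.csv` (wide summary),
#' `replicates.csv` (long, per replicate) and a manifest.
#'
#' @param out_dir Output directory.
#' @param config Optional config file path.
#' @param thetas,ns Grid axes.
#' @param reps Replicates per scenario.
#' @param seed Master seed.
#' @param models Models to run.
#' @param chains,warmup,iter Bayesian sampler settings.
#' @param bnb_prediction Prediction mode for the Bayesian metrics.
#' @param verbose Print progress.
#' @return The wide summary table, invisibly.
#' @export
cmd_study <- function(out_dir, config = NULL, thetas = NULL, ns = NULL,
                      reps = NULL, seed = NULL, models = c("nb", "bnb"),
                      chains = 2, warmup = 500, iter = 500,
                      bnb_prediction = "single_draw", verbose = FALSE) {
  cfg <- if (!is.null(config)) read_config(config) else list()
  thetas <- thetas %||% cfg_get(cfg, "thetas", c(1.5, 5, 10, 100))
  ns <- ns %||% cfg_get(cfg, "ns", c(60, 120, 240, 360))
  reps <- reps %||% cfg_get(cfg, "reps", 10)
  seed <- seed %||% cfg_get(cfg, "seed", 76568)
  sp <- specs_from_config(cfg)
  dir.create(file.path(out_dir, "checkpoints"), recursive = TRUE,
             showWarnings = FALSE)
  grid <- scenario_grid(thetas, ns, n_replicates = reps, master_seed = seed)
  rep_list <- list()
  for (sc in grid) {
    ck <- file.path(out_dir, "checkpoints",
                    sprintf("rep_theta%g_n%d.csv", sc$theta, sc$n))
    if (file.exists(ck)) {
      rep_list[[length(rep_list) + 1L]] <- read.csv(ck)
      next
    }
    res <- run_simulation_study(
      grid = list(sc), tn = sp$tn, rain = sp$rain, count = sp$count,
      models = models, reps = reps, chains = chains, warmup = warmup,
      iter = iter, bnb_prediction = bnb_prediction, verbose = verbose)
    write.csv(res$replicates, ck, row.names = FALSE)
    rep_list[[length(rep_list) + 1L]] <- res$replicates
  }
  replicates <- do.call(rbind, rep_list)
  records <- aggregate(
    replicates[c("bias_pct", "mase", "rmse_train", "rmse_test")],
    by = replicates[c("theta", "n", "model")], FUN = mean)
  wide <- summarize_study(records)
  # order rows theta-major to match the grid
  wide <- wide[order(match(paste(wide$theta, wide$n),
                           vapply(grid, function(s) paste(s$theta, s$n),
                                  ""))), ]
  rownames(wide) <- NULL
  write.csv(wide, file.path(out_dir, "table1.csv"), row.names = FALSE)
  write.csv(replicates, file.path(out_dir, "replicates.csv"),
            row.names = FALSE)
  write_manifest(out_dir, "study",
                 params = list(thetas = thetas, ns = ns, reps = reps,
                               seed = seed, models = models, chains = chains,
                               warmup = warmup, iter = iter,
                               bnb_prediction = bnb_prediction,
                               tn = unclass(sp$tn), rain = unclass(sp$rain),
                               count = unclass(sp$count)),
                 outputs = c("table1.csv", "replicates.csv"))
  invisible(wide)
}

#' Aggregate hotspot and climate CSVs into the modelling table
#'
#' Reads a FIRMS-style hotspot CSV and a monthly climate CSV
#' (`year,month,rainfall,tmin,tmax`), aggregates hotspots by calendar month
#' (keeping the requested type codes), joins the two on `(year, month)`,
#' writes the modelling CSV and prints a summary-statistics block
#' (min/max/median/mean/SD per variable).
#'
#' @param firms_csv Path to the hotspot CSV.
#' @param climate_csv Path to the monthly climate CSV.
#' @param out Output modelling CSV path.
#' @param types Fire type codes to keep (default 0).
#' @param quiet Suppress the summary block.
#' @return The modelling `data.frame`, invisibly.
#' @export
cmd_aggregate <- function(firms_csv, climate_csv, out, types = 0L,
                          quiet = FALSE) {
  records <- read_firms_csv(firms_csv)
  climate <- read.csv(climate_csv)
  monthly <- aggregate_monthly(records, types = types)
  tab <- merge_climate(monthly, climate)
  write.csv(tab, out, row.names = FALSE)
  if (!quiet) {
    vars <- c("fire_count", "max_temp", "tmin", "rainfall")
    cat(sprintf("Summary of modelling dataset (n = %d)\n", nrow(tab)))
    cat(sprintf("%-12s %10s %10s %10s %10s %10s\n", "variable", "min", "max",
                "median", "mean", "sd"))
    for (v in vars) {
      x <- tab[[v]]
      cat(sprintf("%-12s %10.2f %10.2f %10.2f %10.2f %10.2f\n", v,
                  min(x), max(x), stats::median(x), mean(x), sd(x)))
    }
  }
  invisible(tab)
}
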