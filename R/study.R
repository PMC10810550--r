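# Scenario x replicate simulation-study harness.

#' Run the simulation study over a scenario grid
#'
#' For every scenario and replicate: generate a series, split it sequentially
#' 80:20 (by default), fit each requested model on the training segment,
#' predict both segments, and record percent bias (test), MASE (test), and
#' RMSE (train and test). Records are averaged over replicates per scenario
#' and model. The whole run is deterministic given the grid's master seed.
#'
#' For the Bayesian model the test/train predictions entering the metrics are,
#' by default, a single posterior-predictive draw
#' ([posterior_predictive_draw()] with `mode = "single_draw"`); set
#' `bnb_prediction = "posterior_mean"` to use the posterior mean instead.
#'
#' Replicate-level fit failures are excluded from the averages and reported in
#' the `exclusions` table; a scenario-model arm with more than
#' `max_failure_rate` failures aborts the study.
#'
#' @param grid A list of [scenario_config()]s, e.g. from [scenario_grid()].
#' @param tn,rain,count Generator specifications (see [generate_series()]).
#' @param models Character subset of `c("nb", "bnb")`.
#' @param reps Replicates per scenario; `NULL` uses each scenario's own
#'   `n_replicates`.
#' @param split_ratio Training fraction for the sequential split.
#' @param bnb_prediction `"single_draw"` or `"posterior_mean"`.
#' @param chains,warmup,iter Sampler settings for the Bayesian fits (short
#'   chains by default, sized for many replicates).
#' @param max_failure_rate Maximum tolerated fraction of failed replicates in
#'   any scenario-model arm (default 0.2).
#' @param verbose Print per-scenario progress.
#' @return A list with `records` (aggregated, one row per scenario x model),
#'   `replicates` (long, one row per scenario x replicate x model) and
#'   `exclusions` (failed replicates with reasons).
#' @export
run_simulation_study <- function(grid = scenario_grid(),
                                 tn = trunc_normal_spec(),
                                 rain = rainfall_spec(),
                                 count = count_spec(),
                                 models = c("nb", "bnb"),
                                 reps = NULL,
                                 split_ratio = 0.8,
                                 bnb_prediction = c("single_draw",
                                                    "posterior_mean"),
                                 chains = 2, warmup = 500, iter = 500,
                                 max_failure_rate = 0.2,
                                 verbose = FALSE) {
  models <- match.arg(models, c("nb", "bnb"), several.ok = TRUE)
  bnb_prediction <- match.arg(bnb_prediction)
  if (!is.null(reps) && reps < 1) stop("`reps` must be >= 1", call. = FALSE)

  rep_rows <- list()
  excl_rows <- list()
  for (sc in grid) {
    n_rep <- if (is.null(reps)) sc$n_replicates else as.integer(reps)
    if (verbose) {
      message(sprintf("scenario theta=%g n=%d (%d replicates)",
                      sc$theta, sc$n, n_rep))
    }
    for (r in seq_len(n_rep)) {
      sc_r <- sc
      sc_r$n_replicates <- max(sc$n_replicates, n_rep)
      series <- generate_series(sc_r, r, tn = tn, rain = rain, count = count)
      sp <- sequential_split(series, split_ratio)
      for (model in models) {
        res <- tryCatch(
          eval_one(model, sp, sc, r, bnb_prediction, chains, warmup, iter),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          excl_rows[[length(excl_rows) + 1L]] <- data.frame(
            theta = sc$theta, n = sc$n, replicate = r, model = model,
            reason = conditionMessage(res))
        } else {
          rep_rows[[length(rep_rows) + 1L]] <- data.frame(
            theta = sc$theta, n = sc$n, replicate = r, model = model,
            bias_pct = res["bias_pct"], mase = res["mase"],
            rmse_train = res["rmse_train"], rmse_test = res["rmse_test"],
            row.names = NULL)
        }
      }
    }
  }
  replicates <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(theta = numeric(), n = integer(), replicate = integer(),
               model = character(), bias_pct = numeric(), mase = numeric(),
               rmse_train = numeric(), rmse_test = numeric())
  exclusions <- if (length(excl_rows)) do.call(rbind, excl_rows) else
    data.frame(theta = numeric(), n = integer(), replicate = integer(),
               model = character(), reason = character())

  # failure-rate audit per scenario-model arm
  for (sc in grid) {
    n_rep <- if (is.null(reps)) sc$n_replicates else as.integer(reps)
    for (model in models) {
      nf <- sum(exclusions$theta == sc$theta & exclusions$n == sc$n &
                  exclusions$model == model)
      if (nf / n_rep > max_failure_rate) {
        stop(sprintf(
          "scenario theta=%g n=%d model=%s: %d/%d replicates failed",
          sc$theta, sc$n, model, nf, n_rep), call. = FALSE)
      }
    }
  }
  if (nrow(exclusions) > 0) {
    message(sprintf("%d replicate fit(s) excluded from the averages",
                    nrow(exclusions)))
  }

  agg <- aggregate(
    replicates[c("bias_pct", "mase", "rmse_train", "rmse_test")],
    by = replicates[c("theta", "n", "model")], FUN = mean)
  # restore grid (theta-major) and model ordering
  agg <- agg[order(match(paste(agg$theta, agg$n),
                         vapply(grid, function(s) paste(s$theta, s$n), "")),
                   agg$model), ]
  rownames(agg) <- NULL
  list(records = agg, replicates = replicates, exclusions = exclusions)
}

# metrics for one model on one split replicate
eval_one <- function(model, sp, sc, r, bnb_prediction, chains, warmup, iter) {
  if (model == "nb") {
    fit <- fit_nb(sp$train)
    p_train <- predict_mean(fit, sp$train)
    p_test <- predict_mean(fit, sp$test)
  } else {
    fit <- suppressWarnings(fit_bnb(
      sp$train, chains = chains, warmup = warmup, iter = iter,
      seed = replicate_seed(sc$master_seed + 1L, sc$n, r)))
    if (bnb_prediction == "single_draw") {
      pr <- withr::with_seed(
        replicate_seed(sc$master_seed + 2L, sc$n, r), {
          list(train = posterior_predictive_draw(fit, sp$train, "single_draw"),
               test = posterior_predictive_draw(fit, sp$test, "single_draw"))
        })
      p_train <- pr$train
      p_test <- pr$test
    } else {
      p_train <- predict_mean(fit, sp$train)
      p_test <- predict_mean(fit, sp$test)
    }
  }
  c(bias_pct = percent_bias(sp$test$fire_count, p_test),
    mase = mase(sp$test$fire_count, p_test, sp$train$fire_count),
    rmse_train = rmse(sp$train$fire_count, p_train),
    rmse_test = rmse(sp$test$fire_count, p_test))
}

#' Wide scenario-by-model summary table
#'
#' Reshapes the aggregated study records into one row per `(theta, n)` with
#' paired model columns (`bnb_bias, nb_bias, bnb_mase, nb_mase, bnb_rmse_train,
#' nb_rmse_train, bnb_rmse_test, nb_rmse_test`), the layout used to report
#' the simulation results.
#'
#' @param records Aggregated records from [run_simulation_study()].
#' @return A wide `data.frame`, CSV-ready.
#' @export
summarize_study <- function(records) {
  if (is.list(records) && !is.data.frame(records) &&
      !is.null(records$records)) {
    records <- records$records
  }
  if (nrow(records) == 0) stop("no records to summarise", call. = FALSE)
  need <- c("nb", "bnb")
  have <- unique(records$model)
  if (!all(need %in% have)) {
    stop("missing model arm(s): ", paste(setdiff(need, have), collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(records[c("theta", "n")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    th <- keys$theta[i]; n <- keys$n[i]
    pick <- function(model, col) {
      v <- records[records$theta == th & records$n == n &
                     records$model == model, col]
      if (length(v) != 1L) stop(sprintf(
        "missing %s arm for theta=%g n=%d", model, th, n), call. = FALSE)
      v
    }
    data.frame(theta = th, n = n,
               bnb_bias = pick("bnb", "bias_pct"),
               nb_bias = pick("nb", "bias_pct"),
               bnb_mase = pick("bnb", "mase"),
               nb_mase = pick("nb", "mase"),
               bnb_rmse_train = pick("bnb", "rmse_train"),
               nb_rmse_train = pick("nb", "rmse_train"),
               bnb_rmse_test = pick("bnb", "rmse_test"),
               nb_rmse_test = pick("nb", "rmse_test"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
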