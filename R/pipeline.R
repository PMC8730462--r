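#' Configuration for an end-to-end pipeline run
#'
#' Bundles the stage configurations. All randomness flows from the single
#' root `seed`: the simulator, the train/test split, cross-validation and
#' model training each receive a seed derived from it, so one integer
#' reproduces a run.
#'
#' @param horizon_minutes 5 or 30; horizon 30 downsamples the 5-minute grid
#'   by a factor of 6.
#' @param lags Prior inputs per prediction (default 2).
#' @param seed Root seed.
#' @param cohort A [cohort_config()] for the simulation stage (its seed is
#'   overridden by the derived stage seed).
#' @param forecaster A [swift_config()] template; lags/horizon/seed are
#'   overridden for consistency with this run.
#' @param test_fraction Fraction of stays held out for per-stay evaluation.
#' @param do_cv Run 3-fold CV before final training.
#' @param cv_grid,cv_widths Passed to [swift_cv()] when `do_cv` is `TRUE`.
#' @param min_points Inclusion threshold (default 61 points on the 5-min grid).
#' @param window Causal smoothing window (default 5).
#' @param include_boundary Hypoxemia tie rule, see [classify_hypoxemia()].
#' @return A `run_config` list.
#' @export
run_config <- function(horizon_minutes = 5, lags = 2L, seed = 1L,
                       cohort = cohort_config(),
                       forecaster = swift_config(),
                       test_fraction = 0.3, do_cv = FALSE,
                       cv_grid = NULL, cv_widths = NULL,
                       min_points = 61L, window = 5L,
                       include_boundary = FALSE) {
  if (!horizon_minutes %in% c(5, 30)) stop("`horizon_minutes` must be 5 or 30", call. = FALSE)
  if (!is_fraction(test_fraction, lo = 0, hi = 1) || test_fraction <= 0) {
    stop("`test_fraction` must lie in (0, 1)", call. = FALSE)
  }
  cohort$seed <- derive_seed(seed, 11L)
  forecaster <- swift_config(
    architecture = forecaster$architecture, lags = as.integer(lags),
    horizon_minutes = horizon_minutes, lstm_widths = forecaster$lstm_widths,
    dropout = forecaster$dropout, learning_rate = forecaster$learning_rate,
    epochs = forecaster$epochs,
    validation_fraction = forecaster$validation_fraction,
    validation_mode = forecaster$validation_mode,
    batch_size = forecaster$batch_size, seed = derive_seed(seed, 12L)
  )
  structure(
    list(horizon_minutes = horizon_minutes, lags = as.integer(lags),
         seed = as.integer(seed), cohort = cohort, forecaster = forecaster,
         test_fraction = test_fraction, do_cv = isTRUE(do_cv),
         cv_grid = cv_grid, cv_widths = cv_widths,
         min_points = as.integer(min_points), window = as.integer(window),
         include_boundary = isTRUE(include_boundary)),
    class = "run_config"
  )
}

#' Run the full pipeline: simulate, preprocess, train, predict, evaluate
#'
#' Executes the stages in order, writing every intermediate artifact plus a
#' run manifest to `out_dir`: `cohort.csv`, `processed.csv`,
#' `exclusions.csv`, optional `cv.json`, `model.json`, `predictions.csv`,
#' `metrics.csv`, `evaluation.json` (pooled confusion for the model and the
#' persistence baseline), and `manifest.json`. Stage progress and counts are
#' logged to stderr and `run.log`. A stage failure aborts with the stage
#' name; earlier outputs are retained for debugging.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional input: a `spo2_cohort` or a cohort CSV path. When
#'   `NULL`, the synthetic simulator provides the cohort.
#' @return Invisibly, a list with the fitted model, forecasts, metrics,
#'   pooled results and file paths.
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate (or load) ----------------------------------------------------
  cohort <- stage("simulate", {
    if (is.null(cohort)) {
      log_msg("simulate: generating %d synthetic stays (seed %d)",
              config$cohort$n_stays, config$cohort$seed)
      generate_cohort(config$cohort)
    } else if (is.character(cohort)) {
      log_msg("load: reading cohort from %s", cohort)
      read_cohort_csv(cohort)
    } else cohort
  })
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort_csv(cohort, cohort_path)
  log_msg("simulate: %d stays written to cohort.csv", length(cohort))

  # -- preprocess ------------------------------------------------------------
  prep <- stage("preprocess", preprocess_cohort(
    cohort, horizon_minutes = config$horizon_minutes,
    window = config$window, min_points = config$min_points
  ))
  log_msg("preprocess: %d stays kept, %d excluded (%s)",
          length(prep$series), nrow(prep$exclusions),
          if (nrow(prep$exclusions)) {
            paste(table(prep$exclusions$reason), names(table(prep$exclusions$reason)),
                  collapse = ", ")
          } else "none")
  proc <- do.call(rbind, lapply(prep$series, function(s) {
    data.frame(stay_id = s$stay_id, time_min = s$time_min, p_smoothed = s$p)
  }))
  utils::write.csv(proc, file.path(out_dir, "processed.csv"), row.names = FALSE)
  utils::write.csv(prep$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  if (!length(prep$series)) stop("pipeline stage 'preprocess' failed: no stays survive exclusion", call. = FALSE)

  # -- train/test split ------------------------------------------------------
  n_stay <- length(prep$series)
  n_test <- max(1L, round(config$test_fraction * n_stay))
  if (n_test >= n_stay) stop("pipeline stage 'split' failed: no stays left for training", call. = FALSE)
  test_idx <- with_seed(derive_seed(config$seed, 13L),
                        sort(sample.int(n_stay, n_test)))
  train_series <- prep$series[-test_idx]
  test_series <- prep$series[test_idx]
  log_msg("split: %d training stays, %d test stays", length(train_series),
          length(test_series))

  train_ds <- stage("train", concat_training(
    lapply(train_series, build_supervised, lags = config$lags)
  ))

  # -- optional cross-validation --------------------------------------------
  fc_config <- config$forecaster
  cv <- NULL
  if (config$do_cv) {
    cv <- stage("cv", swift_cv(train_ds, grid = config$cv_grid,
                               config = fc_config, widths = config$cv_widths))
    log_msg("cv: selected %s architecture, learning rate %g",
            cv$selected$architecture, cv$selected$learning_rate)
    fc_config <- swift_config(
      architecture = as.character(cv$selected$architecture),
      lags = fc_config$lags, horizon_minutes = fc_config$horizon_minutes,
      lstm_widths = if (!is.null(config$cv_widths))
        config$cv_widths[[as.character(cv$selected$architecture)]] else NULL,
      dropout = fc_config$dropout,
      learning_rate = cv$selected$learning_rate, epochs = fc_config$epochs,
      validation_fraction = fc_config$validation_fraction,
      validation_mode = fc_config$validation_mode,
      batch_size = fc_config$batch_size, seed = fc_config$seed
    )
    jsonlite::write_json(
      list(grid = cv$grid, fold_mse = cv$fold_mse, mean_mse = cv$mean_mse,
           selected = cv$selected),
      file.path(out_dir, "cv.json"), auto_unbox = TRUE, digits = NA
    )
  }

  # -- final training --------------------------------------------------------
  model <- stage("train", swift(train_ds, fc_config))
  write_swift(model, file.path(out_dir, "model.json"))
  log_msg("train: %d rows, best epoch %d, validation MSE %.3g",
          model$n_obs, model$best_epoch,
          model$history$val_loss[model$best_epoch])

  # -- predict ---------------------------------------------------------------
  forecasts <- stage("predict", predict(model, test_series))
  utils::write.csv(forecasts, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  log_msg("predict: %d one-step forecasts on %d test stays", nrow(forecasts),
          length(test_series))

  # -- evaluate --------------------------------------------------------------
  eval_res <- stage("evaluate", {
    metrics <- cohort_metrics(forecasts, include_boundary = config$include_boundary)
    pooled <- aggregate_confusion(metrics)
    base <- persistence_forecast(test_series, lags = config$lags)
    base_pooled <- aggregate_confusion(
      cohort_metrics(base, include_boundary = config$include_boundary)
    )
    list(metrics = metrics, pooled = pooled, baseline_pooled = base_pooled,
         summary = summarize_cohort(metrics))
  })
  utils::write.csv(eval_res$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(eval_res$summary, file.path(out_dir, "metric_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(model = unclass(eval_res$pooled),
         persistence_baseline = unclass(eval_res$baseline_pooled)),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA
  )
  log_msg("evaluate: pooled sensitivity %.3f, PPV %.3f (persistence: %.3f, %.3f)",
          eval_res$pooled$sensitivity, eval_res$pooled$ppv,
          eval_res$baseline_pooled$sensitivity, eval_res$baseline_pooled$ppv)

  # -- manifest --------------------------------------------------------------
  manifest <- list(
    package = "swiftr",
    package_version = as.character(utils::packageVersion("swiftr")),
    config = unclass_deep(config),
    stage_seeds = list(simulate = config$cohort$seed,
                       split = derive_seed(config$seed, 13L),
                       train = config$forecaster$seed),
    stays = list(simulated = length(cohort), kept = n_stay,
                 excluded = nrow(prep$exclusions),
                 train = length(train_series), test = length(test_series)),
    outputs = c("cohort.csv", "processed.csv", "exclusions.csv",
                if (config$do_cv) "cv.json", "model.json", "predictions.csv",
                "metrics.csv", "metric_summary.csv", "evaluation.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(model = model, cv = cv, forecasts = forecasts,
                 metrics = eval_res$metrics, pooled = eval_res$pooled,
                 baseline_pooled = eval_res$baseline_pooled,
                 exclusions = prep$exclusions, out_dir = out_dir))
}

# Strip S3 classes recursively so configs serialize as plain JSON objects.
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}
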