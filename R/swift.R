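#' Forecaster configuration
#'
#' Hyperparameters of the one-step-ahead LSTM forecaster. The shallow
#' architecture has two LSTM hidden layers (256 then 16 units by default);
#' the deep architecture has five (default 256, 128, 64, 32, 16 — a monotone
#' taper ending at the shallow net's 16; the narrower widths are
#' configurable). Both begin with a batch-normalization input layer, place a
#' dropout layer (ratio 0.1) after every LSTM layer, and end in a single
#' linear output neuron. Training minimizes mean squared error with Adam.
#'
#' @param architecture `"shallow"` (2 LSTM layers) or `"deep"` (5).
#' @param lags Number of prior timepoints used as input (default 2).
#' @param horizon_minutes Forecast horizon: 5 (5-minute grid) or 30
#'   (downsampled 30-minute grid).
#' @param lstm_widths Integer vector of LSTM layer widths; length must match
#'   the architecture (2 or 5). `NULL` uses the architecture default.
#' @param dropout Dropout ratio in \[0, 1) (default 0.1).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs (default 100).
#' @param validation_fraction Fraction of rows held out for validation
#'   (default 0.10).
#' @param validation_mode `"per_epoch"` re-draws the random validation split
#'   every epoch (the literal protocol); `"fixed"` draws it once, which makes
#'   best-epoch selection less noisy.
#' @param batch_size Minibatch size (default 256).
#' @param seed Integer seed; fixes initialization, splits, shuffling and
#'   dropout, making training fully reproducible single-threaded.
#' @return An object of class `swift_config`.
#' @export
swift_config <- function(architecture = c("shallow", "deep"),
                         lags = 2L,
                         horizon_minutes = 5,
                         lstm_widths = NULL,
                         dropout = 0.1,
                         learning_rate = 0.001,
                         epochs = 100L,
                         validation_fraction = 0.10,
                         validation_mode = c("per_epoch", "fixed"),
                         batch_size = 256L,
                         seed = 1L) {
  architecture <- match.arg(architecture)
  validation_mode <- match.arg(validation_mode)
  n_layers <- if (architecture == "shallow") 2L else 5L
  if (is.null(lstm_widths)) {
    lstm_widths <- if (architecture == "shallow") c(256L, 16L)
                   else c(256L, 128L, 64L, 32L, 16L)
  }
  if (length(lstm_widths) != n_layers) {
    stop("`lstm_widths` must have length ", n_layers, " for the ",
         architecture, " architecture", call. = FALSE)
  }
  if (!all(vapply(lstm_widths, function(w) is_count(w), TRUE))) {
    stop("`lstm_widths` must be positive counts", call. = FALSE)
  }
  if (!is_count(lags)) stop("`lags` must be a positive count", call. = FALSE)
  if (!horizon_minutes %in% c(5, 30)) stop("`horizon_minutes` must be 5 or 30", call. = FALSE)
  if (!is_fraction(dropout)) stop("`dropout` must lie in [0, 1)", call. = FALSE)
  if (!is_number(learning_rate) || learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (!is_count(epochs)) stop("`epochs` must be a positive count", call. = FALSE)
  if (!is_fraction(validation_fraction, lo = 0, hi = 1) || validation_fraction <= 0) {
    stop("`validation_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (!is_count(batch_size)) stop("`batch_size` must be a positive count", call. = FALSE)
  structure(
    list(architecture = architecture, lags = as.integer(lags),
         horizon_minutes = as.numeric(horizon_minutes),
         lstm_widths = as.integer(lstm_widths), dropout = as.numeric(dropout),
         learning_rate = as.numeric(learning_rate), epochs = as.integer(epochs),
         validation_fraction = as.numeric(validation_fraction),
         validation_mode = validation_mode,
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "swift_config"
  )
}

#' Fit the one-step-ahead SpO2 forecaster
#'
#' Trains the LSTM regressor on a pooled supervised lag dataset. Each epoch
#' holds out a random `validation_fraction` of rows, shuffles the remainder
#' into minibatches, and takes Adam steps on mean squared error. After the
#' final epoch, the weights recorded at the epoch with the lowest validation
#' loss are restored ("best-epoch restoration"), guarding against
#' overfitting. Training is deterministic given `config$seed`.
#'
#' @param data A `supervised_set` (see [build_supervised()],
#'   [concat_training()]), or a list of `supervised_set`s / smoothed
#'   `p_series` which are pooled automatically.
#' @param config A [swift_config()].
#' @param keep_final Also retain the final-epoch weights (for diagnostics).
#' @return An object of class `swift`: the configuration, trained weights,
#'   per-epoch training/validation loss `history`, `best_epoch`, and training
#'   residuals at the restored weights.
#' @seealso [predict.swift()], [swift_cv()], [persistence_forecast()]
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_stays = 4, seed = 2))
#' prep <- preprocess_cohort(cohort)
#' ds <- concat_training(lapply(prep$series, build_supervised))
#' cfg <- swift_config(lstm_widths = c(8L, 4L), epochs = 5L, seed = 2)
#' fit <- swift(ds, cfg)
#' print(fit)
#' }
#' @export
swift <- function(data, config = swift_config(), keep_final = FALSE) {
  stopifnot(inherits(config, "swift_config"))
  data <- as_supervised(data, config$lags)
  if (nrow(data$X) == 0L) stop("training dataset is empty", call. = FALSE)
  if (data$lags != config$lags) {
    stop("dataset lags (", data$lags, ") do not match config lags (",
         config$lags, ")", call. = FALSE)
  }
  n <- nrow(data$X)
  val_n <- max(1L, round(config$validation_fraction * n))
  if (val_n >= n) stop("dataset too small for the validation split", call. = FALSE)

  fit <- with_seed(config$seed, {
    net <- net_init(config$lags, config$lstm_widths, config$dropout)
    state <- adam_init(net$par)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_loss = numeric(0))
    best <- list(val = Inf, epoch = NA_integer_, par = NULL, running = NULL)
    fixed_val <- if (config$validation_mode == "fixed") sample.int(n, val_n)

    for (epoch in seq_len(config$epochs)) {
      val_idx <- if (config$validation_mode == "fixed") fixed_val
                 else sample.int(n, val_n)
      tr_idx <- sample(setdiff(seq_len(n), val_idx))
      batches <- split(tr_idx, ceiling(seq_along(tr_idx) / config$batch_size))
      tot_loss <- 0
      for (b in batches) {
        Xb <- data$X[b, , drop = FALSE]
        yb <- data$Y[b]
        fw <- net_forward(net, Xb, training = TRUE)
        loss <- mse_loss(fw$yhat, yb)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               "; try a smaller learning rate", call. = FALSE)
        }
        grads <- net_backward(net, fw$cache, mse_grad(fw$yhat, yb))
        upd <- adam_step(net$par, grads, state, config$learning_rate)
        net$par <- upd$par
        state <- upd$state
        net$running <- fw$running
        tot_loss <- tot_loss + loss * length(b)
      }
      train_loss <- tot_loss / length(tr_idx)
      val_pred <- net_forward(net, data$X[val_idx, , drop = FALSE])$yhat
      val_loss <- mse_loss(val_pred, data$Y[val_idx])
      history <- rbind(history, data.frame(epoch = epoch, loss = train_loss,
                                           val_loss = val_loss))
      if (val_loss < best$val) {
        best <- list(val = val_loss, epoch = epoch, par = net$par,
                     running = net$running)
      }
    }
    final_net <- net
    net$par <- best$par
    net$running <- best$running
    list(net = net, final_net = final_net, history = history,
         best_epoch = best$epoch)
  })

  fitted_vals <- net_forward(fit$net, data$X)$yhat
  obj <- structure(
    list(config = config, net = fit$net, history = fit$history,
         best_epoch = fit$best_epoch, n_obs = n,
         stay_boundaries = data$stay_boundaries,
         fitted = fitted_vals, residuals = data$Y - fitted_vals,
         call = match.call()),
    class = "swift"
  )
  if (keep_final) obj$final_net <- fit$final_net
  obj
}

# Coerce the accepted training inputs into one supervised_set.
as_supervised <- function(data, lags) {
  if (inherits(data, "supervised_set")) return(data)
  if (inherits(data, "p_series")) return(build_supervised(data, lags))
  if (is.list(data)) {
    parts <- lapply(data, function(d) {
      if (inherits(d, "supervised_set")) d else build_supervised(d, lags)
    })
    return(concat_training(parts))
  }
  stop("`data` must be a supervised_set, p_series, or list of them", call. = FALSE)
}

#' Number of trainable parameters of a fitted forecaster
#' @param object A `swift` model.
#' @return Integer count (batch-norm scale/shift, LSTM gate weights and
#'   biases, dense output weights).
#' @export
n_parameters <- function(object) {
  stopifnot(inherits(object, "swift"))
  net_n_params(object$net)
}

#' @export
print.swift <- function(x, ...) {
  cat(sprintf("SWIFT one-step-ahead SpO2 forecaster (%d-minute horizon)\n",
              x$config$horizon_minutes))
  cat(sprintf("  architecture: %s LSTM [%s], dropout %.2g, %d lags\n",
              x$config$architecture,
              paste(x$config$lstm_widths, collapse = ", "),
              x$config$dropout, x$config$lags))
  cat(sprintf("  trained %d epochs on %d rows; best epoch %d (val MSE %.3g)\n",
              nrow(x$history), x$n_obs, x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.swift <- function(object, ...) {
  res <- list(
    config = object$config,
    n_obs = object$n_obs,
    n_parameters = n_parameters(object),
    best_epoch = object$best_epoch,
    best_val_loss = object$history$val_loss[object$best_epoch],
    final_train_loss = object$history$loss[nrow(object$history)],
    train_mse = if (is.null(object$residuals)) NA_real_ else mean(object$residuals^2),
    n_stays = if (is.null(object$stay_boundaries)) NA_integer_ else nrow(object$stay_boundaries)
  )
  class(res) <- "summary.swift"
  res
}

#' @export
print.summary.swift <- function(x, ...) {
  cat("SWIFT forecaster summary\n")
  cat(sprintf("  %s architecture, %s parameters, lags = %d, horizon = %d min\n",
              x$config$architecture, format(x$n_parameters, big.mark = ","),
              x$config$lags, x$config$horizon_minutes))
  cat(sprintf("  trained on %d rows from %d stay(s)\n", x$n_obs, x$n_stays))
  cat(sprintf("  best epoch %d: validation MSE %.4g; training MSE at restored weights %.4g\n",
              x$best_epoch, x$best_val_loss, x$train_mse))
  invisible(x)
}

#' @export
coef.swift <- function(object, ...) object$net$par

#' @export
residuals.swift <- function(object, ...) object$residuals

#' @export
fitted.swift <- function(object, ...) object$fitted

#' Plot training history
#'
#' Training and validation MSE per epoch, with the restored best epoch marked.
#'
#' @param x A `swift` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.swift <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l", lty = 1,
                    col = c("grey40", "firebrick"), xlab = "epoch",
                    ylab = "MSE", main = "SWIFT training history", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation", "best epoch"),
                   lty = c(1, 1, 3), col = c("grey40", "firebrick", "black"),
                   bty = "n")
  invisible(x)
}

#' One-step-ahead prediction
#'
#' Predicts each next value from the *observed* previous `lags` values
#' (teacher forcing; no recursive rollout). For a `p_series` the result is an
#' aligned forecast frame with one row per predictable timepoint
#' (`length - lags` rows). Predictions are clipped to the transform's valid
#' range so they are always inverse-transformable.
#'
#' @param object A fitted `swift` model.
#' @param newdata A smoothed `p_series` at the model's horizon, a list of
#'   them, a `supervised_set`, or a numeric matrix of lag rows.
#' @param type `"p"` (transformed scale, default), `"spo2"` (percent), or
#'   `"class"` (logical hypoxemia labels at the 92% threshold).
#' @param ... Unused.
#' @return For series input: a data frame (`stay_id`, `time_min`, `p_true`,
#'   `p_pred`, plus converted columns for other `type`s), class
#'   `swift_forecast`. For matrix/`supervised_set` input: a numeric (or
#'   logical) vector.
#' @export
predict.swift <- function(object, newdata, type = c("p", "spo2", "class"), ...) {
  type <- match.arg(type)
  predict_any(object, newdata, type)
}

predict_any <- function(object, newdata, type) {
  cfg <- object$config
  if (is.matrix(newdata)) {
    if (ncol(newdata) != cfg$lags) {
      stop("input matrix must have ", cfg$lags, " columns", call. = FALSE)
    }
    p <- clip_p(net_forward(object$net, newdata)$yhat)
    return(convert_pred(p, type))
  }
  if (inherits(newdata, "supervised_set")) {
    if (newdata$lags != cfg$lags) {
      stop("dataset lags do not match the model", call. = FALSE)
    }
    p <- clip_p(net_forward(object$net, newdata$X)$yhat)
    return(convert_pred(p, type))
  }
  if (inherits(newdata, "p_series")) {
    return(forecast_series(object, newdata, type))
  }
  if (is.list(newdata)) {
    frames <- lapply(newdata, function(s) forecast_series(object, s, type))
    out <- do.call(rbind, frames)
    class(out) <- c("swift_forecast", "data.frame")
    return(out)
  }
  stop("unsupported `newdata` type", call. = FALSE)
}

forecast_series <- function(object, series, type) {
  cfg <- object$config
  if (!is.null(series$interval_minutes) &&
      series$interval_minutes != cfg$horizon_minutes) {
    stop("series interval (", series$interval_minutes,
         " min) does not match the model horizon (", cfg$horizon_minutes,
         " min)", call. = FALSE)
  }
  n <- length(series$p)
  if (n < cfg$lags + 1L) {
    warning("stay '", series$stay_id, "' too short to predict (", n,
            " points); returning empty forecast", call. = FALSE)
    out <- data.frame(stay_id = character(0), time_min = numeric(0),
                      p_true = numeric(0), p_pred = numeric(0))
    class(out) <- c("swift_forecast", "data.frame")
    return(out)
  }
  ds <- build_supervised(series, cfg$lags)
  p_pred <- clip_p(net_forward(object$net, ds$X)$yhat)
  out <- data.frame(stay_id = ds$stay_id, time_min = ds$time_min,
                    p_true = ds$Y, p_pred = p_pred,
                    stringsAsFactors = FALSE)
  if (type == "spo2") {
    out$spo2_true <- inverse_transform_spo2(out$p_true)
    out$spo2_pred <- inverse_transform_spo2(out$p_pred)
  } else if (type == "class") {
    out$hypox_true <- classify_hypoxemia(out$p_true)
    out$hypox_pred <- classify_hypoxemia(out$p_pred)
  }
  class(out) <- c("swift_forecast", "data.frame")
  out
}

clip_p <- function(p) pmin(pmax(p, 0), p_range_max())

convert_pred <- function(p, type) {
  switch(type,
         p = p,
         spo2 = inverse_transform_spo2(p),
         class = classify_hypoxemia(p))
}

#' Persistence baseline forecast
#'
#' The naive forecaster that predicts the next value equals the most recent
#' observed value. Aligned exactly like [predict.swift()] on a series (first
#' `lags` points are not scored), so the two are directly comparable.
#'
#' @param series A `p_series` or list of them.
#' @param lags Alignment offset matching the model being compared (default 2).
#' @return A `swift_forecast` data frame.
#' @export
persistence_forecast <- function(series, lags = 2L) {
  if (inherits(series, "p_series")) series <- list(series)
  frames <- lapply(series, function(s) {
    n <- length(s$p)
    if (n < lags + 1L) {
      return(data.frame(stay_id = character(0), time_min = numeric(0),
                        p_true = numeric(0), p_pred = numeric(0)))
    }
    idx <- (lags + 1L):n
    data.frame(stay_id = rep(s$stay_id, length(idx)),
               time_min = s$time_min[idx],
               p_true = s$p[idx], p_pred = s$p[idx - 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, frames)
  class(out) <- c("swift_forecast", "data.frame")
  out
}

#' 3-fold cross-validation over architecture and learning rate
#'
#' Grid search following the selection protocol: every candidate
#' (architecture, learning rate) is trained on `folds - 1` folds and scored
#' by MSE on the held-out fold; the candidate with the lowest average MSE
#' across folds is selected. The default grid crosses the shallow and deep
#' architectures with Adam learning rates 0.001, 0.01 and 0.1.
#'
#' @param data A `supervised_set` (or list coercible to one).
#' @param grid Data frame with columns `architecture`, `learning_rate`;
#'   `NULL` for the default 2 x 3 grid.
#' @param folds Number of folds (default 3).
#' @param config Base [swift_config()]; architecture/learning rate are
#'   overridden per candidate, everything else (lags, epochs, seed, ...) is
#'   shared.
#' @param widths Named list with `shallow` and `deep` width vectors, so CV
#'   can be run with reduced capacity. `NULL` uses architecture defaults.
#' @param by_stay Assign whole stays to folds (prevents within-stay leakage);
#'   default `FALSE` assigns pooled rows, matching the concatenated training
#'   vector.
#' @return An object of class `swift_cv`: the grid, the candidate x fold MSE
#'   matrix, per-candidate means, and the selected row.
#' @export
swift_cv <- function(data, grid = NULL, folds = 3L, config = swift_config(),
                     widths = NULL, by_stay = FALSE) {
  data <- as_supervised(data, config$lags)
  if (!is_count(folds, min = 2L)) stop("`folds` must be at least 2", call. = FALSE)
  n <- nrow(data$X)
  if (n < folds * 2L) stop("dataset too small for ", folds, "-fold CV", call. = FALSE)
  if (is.null(grid)) {
    grid <- expand.grid(architecture = c("shallow", "deep"),
                        learning_rate = c(0.001, 0.01, 0.1),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("architecture", "learning_rate") %in% names(grid)))

  fold_of <- with_seed(derive_seed(config$seed, 1L), {
    if (by_stay) {
      ids <- data$stay_boundaries$stay_id
      stay_fold <- sample(rep(seq_len(folds), length.out = length(ids)))
      stay_fold[match(data$stay_id, ids)]
    } else {
      sample(rep(seq_len(folds), length.out = n))
    }
  })

  fold_mse <- matrix(NA_real_, nrow(grid), folds)
  for (ci in seq_len(nrow(grid))) {
    arch <- as.character(grid$architecture[ci])
    w <- if (!is.null(widths)) widths[[arch]] else NULL
    cand_cfg <- swift_config(
      architecture = arch, lags = config$lags,
      horizon_minutes = config$horizon_minutes, lstm_widths = w,
      dropout = config$dropout, learning_rate = grid$learning_rate[ci],
      epochs = config$epochs,
      validation_fraction = config$validation_fraction,
      validation_mode = config$validation_mode,
      batch_size = config$batch_size,
      seed = derive_seed(config$seed, 100L + ci)
    )
    for (k in seq_len(folds)) {
      tr <- fold_of != k
      ds_tr <- supervised_set(data$lags, data$X[tr, , drop = FALSE],
                              data$Y[tr], data$stay_id[tr], data$time_min[tr])
      mse_k <- tryCatch({
        fit <- swift(ds_tr, cand_cfg)
        pred <- net_forward(fit$net, data$X[!tr, , drop = FALSE])$yhat
        mse_loss(pred, data$Y[!tr])
      }, error = function(e) Inf)
      fold_mse[ci, k] <- mse_k
    }
  }
  means <- rowMeans(fold_mse)
  sel <- which.min(means)
  structure(
    list(grid = grid, fold_mse = fold_mse, mean_mse = means,
         selected = grid[sel, , drop = FALSE], selected_index = sel,
         folds = folds),
    class = "swift_cv"
  )
}

#' @export
print.swift_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d candidates\n", x$folds, nrow(x$grid)))
  tab <- cbind(x$grid, mean_mse = signif(x$mean_mse, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("selected: %s, learning rate %g\n",
              x$selected$architecture, x$selected$learning_rate))
  invisible(x)
}

SWIFT_MODEL_FORMAT <- "swiftr-model"
SWIFT_MODEL_VERSION <- 1L

#' Save / load a trained forecaster
#'
#' The model is stored as a single JSON file: a version tag, the
#' configuration, training history, best epoch, and all weights at full
#' precision. `read_swift(write_swift(m))` reproduces predictions exactly.
#'
#' @param object A fitted `swift` model.
#' @param path File path.
#' @return `write_swift` returns `path` invisibly; `read_swift` returns the
#'   restored `swift` object.
#' @export
write_swift <- function(object, path) {
  stopifnot(inherits(object, "swift"))
  ser_par <- lapply(object$net$par, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.numeric(p))
  })
  payload <- list(
    format = SWIFT_MODEL_FORMAT,
    version = SWIFT_MODEL_VERSION,
    config = unclass(object$config),
    history = object$history,
    best_epoch = object$best_epoch,
    n_obs = object$n_obs,
    widths = object$net$widths,
    running = object$net$running,
    par = ser_par
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_swift
#' @export
read_swift <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("cannot read model file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
                      })
  if (!identical(payload$format, SWIFT_MODEL_FORMAT) ||
      !identical(as.integer(payload$version), SWIFT_MODEL_VERSION)) {
    stop("'", path, "' is not a recognized swiftr model file ",
         "(format/version tag mismatch)", call. = FALSE)
  }
  cfg <- payload$config
  config <- swift_config(
    architecture = cfg$architecture, lags = cfg$lags,
    horizon_minutes = cfg$horizon_minutes, lstm_widths = cfg$lstm_widths,
    dropout = cfg$dropout, learning_rate = cfg$learning_rate,
    epochs = cfg$epochs, validation_fraction = cfg$validation_fraction,
    validation_mode = cfg$validation_mode, batch_size = cfg$batch_size,
    seed = cfg$seed
  )
  par <- lapply(payload$par, function(p) {
    if (length(p$dim) == 2L) matrix(p$data, p$dim[1], p$dim[2]) else p$data
  })
  net <- list(lags = config$lags, widths = as.integer(payload$widths),
              dropout = config$dropout, par = par,
              running = list(mean = payload$running$mean,
                             var = payload$running$var))
  structure(
    list(config = config, net = net, history = payload$history,
         best_epoch = payload$best_epoch, n_obs = payload$n_obs,
         stay_boundaries = NULL, fitted = NULL, residuals = NULL,
         call = NULL),
    class = "swift"
  )
}
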