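#' Regularize a stay onto a uniform time grid
#'
#' Resamples a possibly irregular, possibly gappy observation record onto a
#' uniform grid (default 5 minutes) running from the stay's first to last
#' timestamp. Each grid point takes the most recent valid observation at or
#' before it (forward fill); grid points before the first valid observation
#' are backfilled with the first available value. The output contains no
#' missing values.
#'
#' @param stay A `stay_series`.
#' @param interval_minutes Grid spacing in minutes (default 5).
#' @return A `stay_series` on the uniform grid with `interval` set.
#' @export
regularize_series <- function(stay, interval_minutes = 5) {
  stopifnot(inherits(stay, "stay_series"))
  if (!is_number(interval_minutes) || interval_minutes <= 0) {
    stop("`interval_minutes` must be positive", call. = FALSE)
  }
  valid <- !is.na(stay$spo2)
  if (!any(valid)) {
    stop("stay '", stay$stay_id, "' has entirely blank SpO2", call. = FALSE)
  }
  vt <- stay$time_min[valid]
  vv <- stay$spo2[valid]
  grid <- seq(stay$time_min[1], stay$time_min[length(stay$time_min)],
              by = interval_minutes)
  idx <- findInterval(grid, vt)
  out <- ifelse(idx == 0L, vv[1], vv[pmax(idx, 1L)])
  stay_series(stay$stay_id, grid, out, cohort_label = stay$cohort_label,
              events = stay$events, interval = interval_minutes)
}

#' Apply cohort exclusion rules
#'
#' Drops stays with entirely blank SpO2 (reason `"blank"`) and stays with
#' fewer than `min_points` grid points — the default 61 corresponds to five
#' hours of 5-minute data, endpoints inclusive (reason `"too_short"`). Order
#' is preserved and the kept/dropped lists partition the input.
#'
#' @param cohort List of `stay_series` (regularized for the point count to be
#'   meaningful; blank detection works on raw stays too).
#' @param min_points Minimum number of points to keep a stay.
#' @return List with `kept` (a `spo2_cohort`) and `dropped`
#'   (data frame `stay_id`, `reason`).
#' @export
apply_exclusions <- function(cohort, min_points = 61L) {
  if (!is_count(min_points, min = 1L)) stop("`min_points` must be a positive count", call. = FALSE)
  reasons <- vapply(cohort, function(s) {
    if (all(is.na(s$spo2))) "blank"
    else if (length(s$spo2) < min_points) "too_short"
    else NA_character_
  }, "")
  kept <- cohort[is.na(reasons)]
  class(kept) <- c("spo2_cohort", "list")
  dropped <- data.frame(
    stay_id = vapply(cohort[!is.na(reasons)], `[[`, "", "stay_id"),
    reason = reasons[!is.na(reasons)],
    stringsAsFactors = FALSE
  )
  list(kept = kept, dropped = dropped)
}

#' Construct a transformed series
#'
#' Container for a regular-grid series on the modelling (transformed) scale.
#' Normally produced by [transform_series()] and [causal_smooth()]; the
#' constructor is exported so synthetic sequences can be fed to the
#' forecaster directly.
#'
#' @param stay_id Stay identifier.
#' @param time_min Timestamps in minutes.
#' @param p Transformed values in \[0, 1 - exp(-10)\].
#' @param interval_minutes Grid interval (5 or 30 for model input).
#' @param smoothed Whether the causal filter has been applied.
#' @param cohort_label Optional sub-population label.
#' @return An object of class `p_series`.
#' @export
p_series <- function(stay_id, time_min, p, interval_minutes, smoothed = FALSE,
                     cohort_label = "unlabelled") {
  stopifnot(length(time_min) == length(p))
  structure(
    list(stay_id = as.character(stay_id), time_min = as.numeric(time_min),
         p = as.numeric(p), interval_minutes = interval_minutes,
         smoothed = isTRUE(smoothed), cohort_label = cohort_label),
    class = "p_series"
  )
}

#' @export
print.p_series <- function(x, ...) {
  cat(sprintf("<p_series> %s: %d points @ %g min, %ssmoothed\n",
              x$stay_id, length(x$p), x$interval_minutes,
              if (x$smoothed) "" else "un"))
  invisible(x)
}

#' Transform a regularized stay to the modelling scale
#'
#' @param stay A regularized `stay_series` (no missing values).
#' @return A `p_series` (unsmoothed).
#' @export
transform_series <- function(stay) {
  stopifnot(inherits(stay, "stay_series"))
  if (anyNA(stay$spo2)) {
    stop("regularize before transforming: series contains missing values", call. = FALSE)
  }
  if (is.null(stay$interval)) {
    stop("series has no uniform interval; regularize first", call. = FALSE)
  }
  p_series(stay$stay_id, stay$time_min, transform_spo2(stay$spo2),
           interval_minutes = stay$interval, smoothed = FALSE,
           cohort_label = stay$cohort_label)
}

#' Causal moving-average smoothing
#'
#' Window-5 causal filter: `out[i] = mean(x[(i-4):i])` for `i >= 5` (1-based).
#' The first `window - 1` points pass through unsmoothed, since a full causal
#' window is not yet available. Being causal, the filter can be applied in
#' real time: no output depends on later inputs. Setting `partial = TRUE`
#' replaces the pass-through rule with expanding-window means.
#'
#' @param x A `p_series` or numeric vector.
#' @param window Window length (default 5).
#' @param partial Use expanding-window means for the first `window - 1` points.
#' @return Same type as `x`, smoothed.
#' @export
causal_smooth <- function(x, window = 5L, partial = FALSE) {
  if (!is_count(window, min = 1L)) stop("`window` must be a positive count", call. = FALSE)
  smooth_vec <- function(v) {
    if (length(v) < window) {
      if (partial && length(v)) return(cumsum(v) / seq_along(v))
      return(v)
    }
    out <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 1))
    head_idx <- seq_len(window - 1L)
    out[head_idx] <- if (partial) cumsum(v[head_idx]) / head_idx else v[head_idx]
    out
  }
  if (inherits(x, "p_series")) {
    if (x$smoothed) warning("series already smoothed; smoothing again", call. = FALSE)
    out <- x
    out$p <- smooth_vec(x$p)
    out$smoothed <- TRUE
    return(out)
  }
  smooth_vec(as.numeric(x))
}

#' Downsample a series by keeping every k-th point
#'
#' Keeps indices 1, 1+factor, 1+2*factor, ... With the default factor 6 a
#' 5-minute series becomes a 30-minute series. Smoothing is applied at the
#' 5-minute resolution before downsampling.
#'
#' @param series A `p_series`.
#' @param factor Positive integer decimation factor.
#' @return A `p_series` at the coarser interval.
#' @export
downsample_series <- function(series, factor = 6L) {
  stopifnot(inherits(series, "p_series"))
  if (!is_count(factor, min = 1L)) stop("`factor` must be a positive count", call. = FALSE)
  if (factor == 1L) return(series)
  keep <- seq(1L, length(series$p), by = factor)
  p_series(series$stay_id, series$time_min[keep], series$p[keep],
           interval_minutes = series$interval_minutes * factor,
           smoothed = series$smoothed, cohort_label = series$cohort_label)
}

#' Rearrange a series into a supervised lag dataset
#'
#' For a series `p_1..p_N` and `lags = L`, builds rows
#' `(p_(t-L), ..., p_(t-1)) -> Y = p_t` for `t = L+1 .. N`, i.e. `N - L` rows.
#' The last column of each X row is the value immediately preceding its
#' target.
#'
#' @param series A smoothed `p_series`.
#' @param lags Number of prior inputs (default 2).
#' @return A `supervised_set`: list with `lags`, matrix `X`, vector `Y`,
#'   `stay_id` per row, `time_min` of each target, and `stay_boundaries`.
#'   A series with `length <= lags` yields an empty dataset with a warning.
#' @export
build_supervised <- function(series, lags = 2L) {
  stopifnot(inherits(series, "p_series"))
  if (!is_count(lags, min = 1L)) stop("`lags` must be a positive count", call. = FALSE)
  n <- length(series$p)
  if (n <= lags) {
    warning("stay '", series$stay_id, "' has ", n,
            " points; need more than ", lags, " - skipped", call. = FALSE)
    return(supervised_set(lags, matrix(numeric(0), 0, lags), numeric(0),
                          character(0), numeric(0)))
  }
  emb <- stats::embed(series$p, lags + 1L)      # row t: p_t, p_{t-1}, ..., p_{t-L}
  X <- emb[, (lags + 1L):2L, drop = FALSE]      # oldest first
  Y <- emb[, 1L]
  supervised_set(lags, X, Y,
                 rep(series$stay_id, nrow(X)),
                 series$time_min[(lags + 1L):n])
}

supervised_set <- function(lags, X, Y, stay_id, time_min) {
  stopifnot(nrow(X) == length(Y))
  ids <- unique(stay_id)
  bounds <- if (length(ids)) {
    data.frame(
      stay_id = ids,
      first_row = vapply(ids, function(i) min(which(stay_id == i)), 1L),
      last_row = vapply(ids, function(i) max(which(stay_id == i)), 1L),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    data.frame(stay_id = character(0), first_row = integer(0), last_row = integer(0))
  }
  structure(
    list(lags = as.integer(lags), X = X, Y = Y, stay_id = stay_id,
         time_min = time_min, stay_boundaries = bounds),
    class = "supervised_set"
  )
}

#' @export
print.supervised_set <- function(x, ...) {
  cat(sprintf("<supervised_set> %d rows x %d lags, %d stay(s)\n",
              nrow(x$X), x$lags, nrow(x$stay_boundaries)))
  invisible(x)
}

#' Concatenate per-stay supervised datasets for pooled training
#'
#' Stacks rows in cohort order; no window ever spans two stays because each
#' dataset was built within a single stay. All inputs must share `lags`.
#'
#' @param datasets List of `supervised_set`s.
#' @return A pooled `supervised_set` with stay provenance recorded.
#' @export
concat_training <- function(datasets) {
  datasets <- Filter(function(d) nrow(d$X) > 0L, datasets)
  if (!length(datasets)) {
    stop("no non-empty supervised datasets to concatenate", call. = FALSE)
  }
  lags <- unique(vapply(datasets, `[[`, 1L, "lags"))
  if (length(lags) != 1L) {
    stop("datasets have mixed lag counts: ", paste(lags, collapse = ", "), call. = FALSE)
  }
  supervised_set(
    lags,
    do.call(rbind, lapply(datasets, `[[`, "X")),
    unlist(lapply(datasets, `[[`, "Y")),
    unlist(lapply(datasets, `[[`, "stay_id")),
    unlist(lapply(datasets, `[[`, "time_min"))
  )
}

#' Full preprocessing pipeline for a cohort
#'
#' Regularizes every stay to the 5-minute grid (blank stays are excluded),
#' applies the inclusion rule (default: at least 61 points, i.e. 5 hours),
#' transforms to the modelling scale, smooths with the window-5 causal
#' filter, and — for the 30-minute horizon — downsamples by 6. Order:
#' transform, smooth, downsample.
#'
#' @param cohort List of `stay_series`.
#' @param horizon_minutes 5 or 30.
#' @param interval_minutes Base grid interval (default 5).
#' @param window Smoothing window (default 5).
#' @param min_points Inclusion threshold on the base grid (default 61).
#' @param smooth_partial Passed to [causal_smooth()].
#' @return List with `series` (list of smoothed `p_series`) and `exclusions`
#'   (data frame `stay_id`, `reason`).
#' @export
preprocess_cohort <- function(cohort, horizon_minutes = 5,
                              interval_minutes = 5, window = 5L,
                              min_points = 61L, smooth_partial = FALSE) {
  if (!horizon_minutes %in% c(5, 30)) {
    stop("`horizon_minutes` must be 5 or 30", call. = FALSE)
  }
  blank <- vapply(cohort, function(s) all(is.na(s$spo2)), TRUE)
  reg <- lapply(cohort[!blank], regularize_series, interval_minutes = interval_minutes)
  scr <- apply_exclusions(reg, min_points = min_points)
  dropped <- rbind(
    data.frame(stay_id = vapply(cohort[blank], `[[`, "", "stay_id"),
               reason = rep("blank", sum(blank)), stringsAsFactors = FALSE),
    scr$dropped
  )
  series <- lapply(scr$kept, function(s) {
    ps <- causal_smooth(transform_series(s), window = window, partial = smooth_partial)
    if (horizon_minutes == 30) ps <- downsample_series(ps, factor = 6L)
    ps
  })
  list(series = series, exclusions = dropped)
}
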