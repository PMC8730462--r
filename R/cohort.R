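#' Configuration for the synthetic ICU SpO2 cohort simulator
#'
#' Describes one simulated sub-population: stay lengths, sampling scheme,
#' desaturation-event process, sensor noise, and missingness. The defaults
#' emulate a critically ill adult cohort monitored by bedside pulse oximetry:
#' baseline saturation near 97%, transient desaturation events arriving as a
#' Poisson process, dips of 5-25 percentage points lasting 10-40 minutes, and
#' 5-minute sampling with a small fraction of dropped readings.
#'
#' @param n_stays Number of patient-stays to simulate.
#' @param stay_length_minutes List with `min`, `median`, `max` (minutes). Stay
#'   lengths are drawn log-normally around the median and clamped to
#'   \[min, max\].
#' @param sampling_interval_minutes Regular sampling interval (minutes).
#' @param event_rate_per_hour Poisson arrival rate of desaturation events.
#' @param event_depth_percent List with `min`, `max`: uniform dip depth below
#'   baseline, in percentage points.
#' @param event_duration_minutes List with `min`, `max`: uniform event
#'   duration in minutes (descent plus recovery).
#' @param baseline_mean_percent Mean baseline saturation, in (85, 100\].
#' @param baseline_sd_percent SD of the per-stay baseline draw.
#' @param noise_sd_percent SD of additive Gaussian sensor noise per reading.
#' @param missing_fraction Fraction of retained timestamps whose SpO2 reading
#'   is missing (independent Bernoulli per timepoint), in \[0, 1).
#' @param irregular If `TRUE`, thin the regular grid geometrically so the
#'   median inter-observation gap is `median_gap_minutes` (emulating
#'   ward-style charting at variable frequency).
#' @param median_gap_minutes Target median gap for irregular sampling.
#' @param event_shape `"exponential"` (piecewise-exponential descent and
#'   recovery, time constant = duration/4) or `"linear"` (triangular dip).
#' @param cohort_label Label attached to every stay (e.g. "ventilated").
#' @param seed Integer root seed; the same config and seed reproduce the
#'   cohort exactly.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_stays = 20L,
                          stay_length_minutes = list(min = 360, median = 720, max = 1440),
                          sampling_interval_minutes = 5,
                          event_rate_per_hour = 0.3,
                          event_depth_percent = list(min = 5, max = 25),
                          event_duration_minutes = list(min = 10, max = 40),
                          baseline_mean_percent = 97,
                          baseline_sd_percent = 1.5,
                          noise_sd_percent = 0.5,
                          missing_fraction = 0.05,
                          irregular = FALSE,
                          median_gap_minutes = 25,
                          event_shape = c("exponential", "linear"),
                          cohort_label = "critical-care",
                          seed = 1L) {
  event_shape <- match.arg(event_shape)
  cfg <- list(
    n_stays = n_stays,
    stay_length_minutes = stay_length_minutes,
    sampling_interval_minutes = sampling_interval_minutes,
    event_rate_per_hour = event_rate_per_hour,
    event_depth_percent = event_depth_percent,
    event_duration_minutes = event_duration_minutes,
    baseline_mean_percent = baseline_mean_percent,
    baseline_sd_percent = baseline_sd_percent,
    noise_sd_percent = noise_sd_percent,
    missing_fraction = missing_fraction,
    irregular = isTRUE(irregular),
    median_gap_minutes = median_gap_minutes,
    event_shape = event_shape,
    cohort_label = as.character(cohort_label),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  rng <- function(x) is.list(x) && is_number(x$min) && is_number(x$max) && x$min <= x$max
  if (!is_count(cfg$n_stays)) stop("`n_stays` must be a positive count", call. = FALSE)
  sl <- cfg$stay_length_minutes
  if (!rng(sl) || !is_number(sl$median %||% NA) ||
      sl$median < sl$min || sl$median > sl$max || sl$min <= 0) {
    stop("`stay_length_minutes` needs positive min <= median <= max", call. = FALSE)
  }
  if (!is_number(cfg$sampling_interval_minutes) || cfg$sampling_interval_minutes <= 0) {
    stop("`sampling_interval_minutes` must be positive", call. = FALSE)
  }
  if (!is_number(cfg$event_rate_per_hour) || cfg$event_rate_per_hour < 0) {
    stop("`event_rate_per_hour` must be nonnegative", call. = FALSE)
  }
  if (!rng(cfg$event_depth_percent) || cfg$event_depth_percent$min < 0) {
    stop("`event_depth_percent` needs 0 <= min <= max", call. = FALSE)
  }
  if (!rng(cfg$event_duration_minutes) || cfg$event_duration_minutes$min <= 0) {
    stop("`event_duration_minutes` needs positive min <= max", call. = FALSE)
  }
  if (!is_number(cfg$baseline_mean_percent) ||
      cfg$baseline_mean_percent <= 85 || cfg$baseline_mean_percent > 100) {
    stop("`baseline_mean_percent` must lie in (85, 100]", call. = FALSE)
  }
  if (!is_number(cfg$baseline_sd_percent) || cfg$baseline_sd_percent < 0) {
    stop("`baseline_sd_percent` must be nonnegative", call. = FALSE)
  }
  if (!is_number(cfg$noise_sd_percent) || cfg$noise_sd_percent < 0) {
    stop("`noise_sd_percent` must be nonnegative", call. = FALSE)
  }
  if (!is_fraction(cfg$missing_fraction)) {
    stop("`missing_fraction` must lie in [0, 1)", call. = FALSE)
  }
  if (!is_number(cfg$median_gap_minutes) || cfg$median_gap_minutes <= 0) {
    stop("`median_gap_minutes` must be positive", call. = FALSE)
  }
  invisible(cfg)
}

# Constructor for a single stay's raw observation record.
stay_series <- function(stay_id, time_min, spo2, cohort_label = "unlabelled",
                        events = NULL, interval = NULL) {
  stopifnot(length(time_min) == length(spo2))
  if (length(time_min) > 1L && any(diff(time_min) <= 0)) {
    stop("`time_min` must be strictly increasing", call. = FALSE)
  }
  ok <- is.na(spo2) | (spo2 >= 0 & spo2 <= 100)
  if (!all(ok)) stop("non-missing SpO2 values must lie in [0, 100]", call. = FALSE)
  structure(
    list(stay_id = as.character(stay_id), time_min = as.numeric(time_min),
         spo2 = as.numeric(spo2), cohort_label = as.character(cohort_label),
         events = events, interval = interval),
    class = "stay_series"
  )
}

#' @export
print.stay_series <- function(x, ...) {
  n_ev <- if (is.null(x$events)) NA_integer_ else nrow(x$events)
  cat(sprintf(
    "<stay_series> %s [%s]: %d obs over %.0f min, %d missing, %s ground-truth events\n",
    x$stay_id, x$cohort_label, length(x$time_min),
    diff(range(x$time_min)), sum(is.na(x$spo2)),
    ifelse(is.na(n_ev), "unknown", n_ev)
  ))
  invisible(x)
}

# Smooth dip profile of one desaturation event evaluated at times t.
# Exponential: descent 1 - exp(-(t-s)/tau) to full depth at mid-event, then
# exponential recovery rescaled to return to zero at event end; tau = dur/4.
event_dip <- function(t, start, duration, depth, shape) {
  mid <- start + duration / 2
  end <- start + duration
  dip <- numeric(length(t))
  if (shape == "linear") {
    inside <- t >= start & t <= end
    dip[inside] <- depth * (1 - abs(t[inside] - mid) / (duration / 2))
    return(dip)
  }
  tau <- duration / 4
  down <- t >= start & t <= mid
  up <- t > mid & t <= end
  norm <- 1 - exp(-(duration / 2) / tau)  # = 1 - exp(-2)
  dip[down] <- depth * (1 - exp(-(t[down] - start) / tau)) / norm
  dip[up] <- depth * (exp(-(t[up] - mid) / tau) - exp(-2)) / norm
  dip
}

#' Simulate one synthetic patient-stay
#'
#' Draws a per-stay baseline saturation, superimposes desaturation events
#' arriving as a Poisson process, adds Gaussian sensor noise, optionally thins
#' the grid to irregular sampling, marks readings missing, and clips to
#' \[0, 100\]. Ground-truth event windows are recorded on the returned series.
#'
#' @param config A [cohort_config()].
#' @param stay_index 1-based index of the stay within the cohort; combined
#'   with `config$seed` it fully determines the stay.
#' @return A `stay_series` with an `events` data frame
#'   (`start_min`, `end_min`, `depth_percent`, `duration_min`) attached.
#' @export
generate_stay <- function(config, stay_index = 1L) {
  validate_cohort_config(config)
  if (!is_count(stay_index)) stop("`stay_index` must be a positive count", call. = FALSE)
  if (stay_index > config$n_stays) {
    stop("`stay_index` exceeds `n_stays`", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, stay_index), {
    dt <- config$sampling_interval_minutes
    sl <- config$stay_length_minutes
    len <- if (sl$min == sl$max) sl$median else {
      stats::qlnorm(stats::runif(1), meanlog = log(sl$median), sdlog = 0.35)
    }
    len <- max(sl$min, min(sl$max, len))
    len <- floor(len / dt) * dt
    times <- seq(0, len, by = dt)

    baseline <- stats::rnorm(1, config$baseline_mean_percent, config$baseline_sd_percent)
    baseline <- min(baseline, 100)

    hours <- len / 60
    n_ev <- stats::rpois(1, config$event_rate_per_hour * hours)
    events <- data.frame(start_min = numeric(0), end_min = numeric(0),
                         depth_percent = numeric(0), duration_min = numeric(0))
    clean <- rep(baseline, length(times))
    if (n_ev > 0) {
      starts <- sort(stats::runif(n_ev, 0, len))
      depths <- stats::runif(n_ev, config$event_depth_percent$min,
                             config$event_depth_percent$max)
      durs <- stats::runif(n_ev, config$event_duration_minutes$min,
                           config$event_duration_minutes$max)
      for (j in seq_len(n_ev)) {
        clean <- clean - event_dip(times, starts[j], durs[j], depths[j],
                                   config$event_shape)
      }
      events <- data.frame(start_min = starts, end_min = starts + durs,
                           depth_percent = depths, duration_min = durs)
    }

    spo2 <- clean + stats::rnorm(length(times), 0, config$noise_sd_percent)

    keep <- rep(TRUE, length(times))
    if (config$irregular) {
      # Geometric thinning: gaps are dt * K with K ~ Geom(p) on {1, 2, ...};
      # p chosen so the median gap equals median_gap_minutes.
      p_keep <- 1 - 2^(-dt / config$median_gap_minutes)
      keep <- stats::runif(length(times)) < p_keep
      keep[1] <- TRUE
    }
    miss <- stats::runif(length(times)) < config$missing_fraction
    spo2[miss] <- NA_real_
    spo2 <- pmin(pmax(spo2, 0), 100)

    stay_series(
      stay_id = sprintf("%s_%03d", config$cohort_label, stay_index),
      time_min = times[keep], spo2 = spo2[keep],
      cohort_label = config$cohort_label, events = events,
      interval = if (config$irregular) NULL else dt
    )
  })
}

#' Simulate a synthetic cohort
#'
#' Generates `n_stays` independent stays from one configuration, or a pooled
#' cohort from several sub-population configurations (e.g. ventilated and
#' non-ventilated groups with different event rates, each with its own
#' `cohort_label`).
#'
#' @param config A [cohort_config()] or a list of them.
#' @return A list of `stay_series`, class `spo2_cohort`.
#' @export
generate_cohort <- function(config) {
  configs <- if (inherits(config, "cohort_config")) list(config) else config
  if (!length(configs) || !all(vapply(configs, inherits, TRUE, "cohort_config"))) {
    stop("`config` must be a cohort_config or a list of them", call. = FALSE)
  }
  labs <- vapply(configs, `[[`, "", "cohort_label")
  if (length(configs) > 1L && anyDuplicated(labs)) {
    stop("sub-population configs must have distinct `cohort_label`s", call. = FALSE)
  }
  cohort <- unlist(lapply(configs, function(cfg) {
    lapply(seq_len(cfg$n_stays), function(i) generate_stay(cfg, i))
  }), recursive = FALSE)
  class(cohort) <- c("spo2_cohort", "list")
  cohort
}

#' @export
print.spo2_cohort <- function(x, ...) {
  n <- vapply(x, function(s) length(s$time_min), 1L)
  cat(sprintf("<spo2_cohort> %d stays, %d-%d observations each, labels: %s\n",
              length(x), min(n), max(n),
              paste(unique(vapply(x, `[[`, "", "cohort_label")), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to tidy CSV
#'
#' Columns `stay_id,time_min,spo2`; missing readings become empty fields.
#' Values round-trip losslessly through [read_cohort_csv()].
#'
#' @param cohort List of `stay_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  lines <- "stay_id,time_min,spo2"
  for (s in cohort) {
    v <- ifelse(is.na(s$spo2), "", vapply(s$spo2, format, "", digits = 17))
    lines <- c(lines, paste(s$stay_id, format(s$time_min, digits = 17, trim = TRUE),
                            v, sep = ","))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read a cohort from tidy CSV
#'
#' Expects header `stay_id,time_min,spo2`. Rows are grouped by `stay_id` in
#' order of first appearance; empty `spo2` fields become missing values;
#' values are validated to \[0, 100\]. Rows out of time order within a stay
#' are sorted with a warning.
#'
#' @param path CSV file path.
#' @return A `spo2_cohort` (list of `stay_series`).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "stay_id,time_min,spo2")) {
    stop("malformed header in '", path, "': expected 'stay_id,time_min,spo2'",
         call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "character"),
                        strip.white = TRUE)
  spo2 <- suppressWarnings(as.numeric(ifelse(df$spo2 == "", NA, df$spo2)))
  bad_parse <- which(df$spo2 != "" & is.na(spo2))
  if (length(bad_parse)) {
    stop("unparseable spo2 value at line ", bad_parse[1] + 1L, " of '", path, "'",
         call. = FALSE)
  }
  bad_rng <- which(!is.na(spo2) & (spo2 < 0 | spo2 > 100))
  if (length(bad_rng)) {
    stop("spo2 value out of [0, 100] at line ", bad_rng[1] + 1L, " of '", path,
         "' (value ", spo2[bad_rng[1]], ")", call. = FALSE)
  }
  ids <- unique(df$stay_id)
  cohort <- lapply(ids, function(id) {
    i <- which(df$stay_id == id)
    tm <- df$time_min[i]
    if (is.unsorted(tm, strictly = TRUE)) {
      warning("observations for stay '", id, "' were not in time order; sorted",
              call. = FALSE)
      o <- order(tm)
      i <- i[o]
      tm <- tm[o]
    }
    stay_series(id, tm, spo2[i])
  })
  class(cohort) <- c("spo2_cohort", "list")
  cohort
}
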