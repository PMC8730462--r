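#' Label timepoints as hypoxemic
#'
#' A timepoint is hypoxemic when SpO2 falls below 92%, i.e. when the
#' transformed value exceeds `1 - exp(-0.8)` (0.55067 to five decimals). The
#' full-precision constant is used; a value at exactly 92% is non-hypoxemic
#' (strict inequality), configurable via `include_boundary`.
#'
#' @param p Numeric vector on the transformed scale.
#' @param include_boundary If `TRUE`, exactly-92% values count as hypoxemic.
#' @return Logical vector, `TRUE` = hypoxemic.
#' @export
classify_hypoxemia <- function(p, include_boundary = FALSE) {
  thr <- hypoxemia_threshold_p()
  if (include_boundary) p >= thr else p > thr
}

#' Per-stay classification and waveform metrics
#'
#' Thresholds true and predicted series identically, counts the confusion
#' cells, and computes accuracy, sensitivity, specificity, PPV, waveform MSE
#' and Pearson correlation (the latter two on the transformed scale).
#' Undefined metrics are reported as `NA`, never as 0: sensitivity is
#' undefined for stays with no true hypoxemic timepoints, specificity for
#' stays with all timepoints hypoxemic, PPV for stays with no positive
#' predictions, and the correlation when either series is constant.
#'
#' @param pred A `swift_forecast` data frame (columns `stay_id`, `p_true`,
#'   `p_pred`) for a single stay.
#' @param include_boundary Tie rule passed to [classify_hypoxemia()].
#' @return One-row data frame: `stay_id`, counts `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `mse`, `pearson_r`.
#' @export
stay_metrics <- function(pred, include_boundary = FALSE) {
  if (!nrow(pred)) stop("empty prediction frame", call. = FALSE)
  if (length(unique(pred$stay_id)) > 1L) {
    stop("`pred` must contain a single stay; use cohort_metrics()", call. = FALSE)
  }
  lt <- classify_hypoxemia(pred$p_true, include_boundary)
  lp <- classify_hypoxemia(pred$p_pred, include_boundary)
  tp <- sum(lt & lp); fp <- sum(!lt & lp)
  tn <- sum(!lt & !lp); fn <- sum(lt & !lp)
  r <- if (stats::sd(pred$p_true) == 0 || stats::sd(pred$p_pred) == 0) {
    NA_real_
  } else {
    stats::cor(pred$p_true, pred$p_pred)
  }
  data.frame(
    stay_id = pred$stay_id[1],
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    mse = mean((pred$p_true - pred$p_pred)^2),
    pearson_r = r,
    stringsAsFactors = FALSE
  )
}

#' Per-stay metrics for a whole forecast frame
#'
#' Splits a pooled forecast frame by stay and applies [stay_metrics()] to
#' each, preserving stay order.
#'
#' @inheritParams stay_metrics
#' @return Data frame with one row per stay, class `swift_metrics`.
#' @export
cohort_metrics <- function(pred, include_boundary = FALSE) {
  ids <- unique(pred$stay_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    stay_metrics(pred[pred$stay_id == id, , drop = FALSE], include_boundary)
  }))
  class(out) <- c("swift_metrics", "data.frame")
  out
}

#' Pooled confusion counts and rates across all timepoints
#'
#' Sums per-stay confusion counts over all stays and reports false positive
#' rate `FP/(FP+TN)`, false negative rate `FN/(FN+TP)`, and pooled accuracy,
#' sensitivity, specificity and PPV computed from the pooled counts.
#'
#' @param stays A `swift_metrics` data frame (from [cohort_metrics()]).
#' @return A list of pooled counts and rates, class `swift_aggregate`.
#' @export
aggregate_confusion <- function(stays) {
  if (!nrow(stays)) stop("no stays to aggregate", call. = FALSE)
  tp <- sum(stays$tp); fp <- sum(stays$fp)
  tn <- sum(stays$tn); fn <- sum(stays$fn)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, n = total,
         false_positive_rate = if (fp + tn == 0) NA_real_ else fp / (fp + tn),
         false_negative_rate = if (fn + tp == 0) NA_real_ else fn / (fn + tp),
         accuracy = (tp + tn) / total,
         sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
         specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
         ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp)),
    class = "swift_aggregate"
  )
}

#' @export
print.swift_aggregate <- function(x, ...) {
  cat(sprintf("Pooled confusion over %d timepoints: TP %d, FP %d, TN %d, FN %d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, PPV %.3f, accuracy %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$accuracy))
  cat(sprintf("  FPR %.4f, FNR %.4f\n", x$false_positive_rate, x$false_negative_rate))
  invisible(x)
}

#' Distribution summary of per-stay metrics
#'
#' For each metric, reports the mean, median, quartiles (type-7 linear
#' interpolation), Tukey whisker bounds (`Q1 - 1.5*IQR`, `Q3 + 1.5*IQR`),
#' the number of outliers beyond the whiskers, and the number of stays
#' excluded because the metric was undefined. Undefined values are excluded
#' from summaries, never treated as zero.
#'
#' @param stays A `swift_metrics` data frame.
#' @param metrics Which metric columns to summarize.
#' @return Data frame, one row per metric.
#' @export
summarize_cohort <- function(stays,
                             metrics = c("accuracy", "sensitivity",
                                         "specificity", "ppv", "mse",
                                         "pearson_r")) {
  rows <- lapply(metrics, function(m) {
    v <- stays[[m]]
    ok <- v[!is.na(v)]
    if (!length(ok)) {
      return(data.frame(metric = m, n = 0L, n_undefined = sum(is.na(v)),
                        mean = NA_real_, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_, n_outliers = NA_integer_))
    }
    q <- stats::quantile(ok, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    data.frame(metric = m, n = length(ok), n_undefined = sum(is.na(v)),
               mean = mean(ok), median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = lo, whisker_hi = hi,
               n_outliers = sum(ok < lo | ok > hi))
  })
  do.call(rbind, rows)
}

#' Do low-sensitivity stays have fewer hypoxemic timepoints?
#'
#' Splits stays with defined sensitivity into those below 0.5 and those at or
#' above 0.5, then compares their mean hypoxemic-event counts with Welch's
#' unequal-variance t-test. By default the event count is `tp + fn` (the
#' number of true hypoxemic timepoints scored for the stay).
#'
#' @param stays A `swift_metrics` data frame.
#' @param event_counts Optional per-stay event counts aligned with `stays`;
#'   defaults to `stays$tp + stays$fn`.
#' @param cutoff Sensitivity cutoff (default 0.5).
#' @return List: group sizes, means, medians, `t`, `df`, `p_value`; or a
#'   `not_computable` report when a group has fewer than two stays.
#' @export
sensitivity_subgroup_test <- function(stays, event_counts = NULL, cutoff = 0.5) {
  if (is.null(event_counts)) event_counts <- stays$tp + stays$fn
  stopifnot(length(event_counts) == nrow(stays))
  def <- !is.na(stays$sensitivity)
  lo <- event_counts[def & stays$sensitivity < cutoff]
  hi <- event_counts[def & stays$sensitivity >= cutoff]
  base <- list(cutoff = cutoff, n_low = length(lo), n_high = length(hi),
               median_low = stats::median(lo), median_high = stats::median(hi),
               mean_low = mean(lo), mean_high = mean(hi))
  if (length(lo) < 2L || length(hi) < 2L) {
    return(c(base, list(computable = FALSE,
                        reason = "a subgroup has fewer than two stays",
                        t = NA_real_, df = NA_real_, p_value = NA_real_)))
  }
  if (stats::var(lo) == 0 && stats::var(hi) == 0) {
    # degenerate constant groups: t = 0 / p = 1 when equal, else separation
    eq <- mean(lo) == mean(hi)
    return(c(base, list(computable = TRUE,
                        t = if (eq) 0 else sign(mean(lo) - mean(hi)) * Inf,
                        df = NA_real_, p_value = if (eq) 1 else 0)))
  }
  tt <- stats::t.test(lo, hi, var.equal = FALSE)
  c(base, list(computable = TRUE, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value))
}

#' Chi-squared test of independence for a 2x2 contingency table
#'
#' Pearson chi-squared test (no continuity correction, df = 1) of
#' independence between a two-level cohort label (e.g. ventilated vs not) and
#' hypoxemic vs non-hypoxemic timepoint counts.
#'
#' @param contingency 2x2 numeric matrix of timepoint counts, rows = cohort
#'   label, columns = hypoxemic / non-hypoxemic.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
ventilation_chisq <- function(contingency) {
  m <- as.matrix(contingency)
  if (!all(dim(m) == c(2L, 2L))) stop("`contingency` must be 2x2", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("a marginal total is zero; the test is undefined", call. = FALSE)
  }
  ct <- stats::chisq.test(m, correct = FALSE)
  if (any(ct$expected <= 0)) stop("expected counts must be positive", call. = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Build the label-by-hypoxemia contingency table for a cohort
#'
#' Counts true hypoxemic and non-hypoxemic timepoints per cohort label from
#' aligned forecast frames, for use with [ventilation_chisq()].
#'
#' @param pred A pooled `swift_forecast` frame.
#' @param labels Named character vector mapping `stay_id` to cohort label.
#' @return 2x2 matrix (rows = labels, cols = c("hypoxemic", "non_hypoxemic")).
#' @export
hypoxemia_contingency <- function(pred, labels) {
  lab <- labels[pred$stay_id]
  if (anyNA(lab)) stop("every stay_id needs a cohort label", call. = FALSE)
  hyp <- classify_hypoxemia(pred$p_true)
  tab <- table(lab, factor(hyp, levels = c(TRUE, FALSE),
                           labels = c("hypoxemic", "non_hypoxemic")))
  m <- matrix(as.numeric(tab), nrow(tab), 2L,
              dimnames = list(rownames(tab), colnames(tab)))
  m
}
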