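test_that("regularization forward-fills onto the 5-minute grid", {
  s <- make_stay(c(0, 25), c(96, 90))
  r <- regularize_series(s)
  expect_identical(r$time_min, seq(0, 25, by = 5))
  expect_identical(r$spo2, c(96, 96, 96, 96, 96, 90))
})

test_that("an already-regular series is unchanged", {
  s <- make_stay(seq(0, 40, by = 5), rep(c(95, 94, 93), length.out = 9))
  r <- regularize_series(s)
  expect_identical(r$time_min, s$time_min)
  expect_identical(r$spo2, s$spo2)
})

test_that("a missing leading value is backfilled with the first available one", {
  s <- make_stay(c(0, 5, 10), c(NA, 94, 92))
  r <- regularize_series(s)
  expect_identical(r$spo2, c(94, 94, 92))
  expect_error(regularize_series(make_stay(c(0, 5), c(NA, NA))), "blank")
})

test_that("exclusion rules drop short and blank stays, partitioning the input", {
  cohort <- list(flat_stay(60, "short"), flat_stay(61, "ok"),
                 make_stay(c(0, 5), c(NA, NA), "empty"))
  scr <- apply_exclusions(cohort)
  expect_identical(vapply(scr$kept, `[[`, "", "stay_id"), "ok")
  expect_identical(scr$dropped$stay_id, c("short", "empty"))
  expect_identical(scr$dropped$reason, c("too_short", "blank"))
  expect_identical(length(scr$kept) + nrow(scr$dropped), length(cohort))

  empty <- apply_exclusions(list())
  expect_length(empty$kept, 0L)
  expect_identical(nrow(empty$dropped), 0L)
})

test_that("causal smoothing matches hand-computed window means", {
  for (k in c(1, 0.1, 0.001)) {
    x <- c(1, 2, 3, 4, 5, 6) * k
    expect_equal(causal_smooth(x), c(1, 2, 3, 4, 3, 4) * k)
  }
  expect_equal(causal_smooth(rep(0.4, 20)), rep(0.4, 20))
  expect_error(causal_smooth(1:10, window = 0), "positive")
})

test_that("smoothing is causal: truncating the tail never changes earlier output", {
  set.seed(4)
  for (i in 1:100) {
    x <- runif(sample(6:40, 1))
    full <- causal_smooth(x)
    m <- sample(seq_along(x), 1)
    expect_identical(causal_smooth(x[seq_len(m)]), full[seq_len(m)])
  }
})

test_that("window-5 smoothing of i.i.d. noise reduces variance about 5-fold", {
  set.seed(5)
  x <- rnorm(2e4)
  sm <- causal_smooth(x)[-(1:4)]
  ratio <- var(x) / var(sm)
  expect_gt(ratio, 4.4)
  expect_lt(ratio, 5.6)
})

test_that("downsampling keeps every 6th point starting at the first", {
  s <- p_series("a", seq(0, by = 5, length.out = 13), seq(0.1, 0.34, by = 0.02),
                interval_minutes = 5, smoothed = TRUE)
  d <- downsample_series(s)
  expect_length(d$p, 3L)
  expect_identical(d$p, s$p[c(1, 7, 13)])
  expect_identical(d$interval_minutes, 30)
  expect_identical(downsample_series(s, factor = 1L), s)
})

test_that("supervised construction follows the X/Y rearrangement", {
  s <- p_series("a", 1:5 * 5, c(0.1, 0.2, 0.3, 0.4, 0.5),
                interval_minutes = 5, smoothed = TRUE)
  ds <- build_supervised(s, lags = 2L)
  expect_identical(unname(ds$X), matrix(c(0.1, 0.2, 0.3, 0.2, 0.3, 0.4), 3, 2))
  expect_identical(ds$Y, c(0.3, 0.4, 0.5))
  expect_identical(ds$time_min, c(15, 20, 25))

  s3 <- p_series("b", 1:3 * 5, c(0.1, 0.2, 0.3), 5, smoothed = TRUE)
  expect_identical(nrow(build_supervised(s3, 2L)$X), 1L)
  ds1 <- build_supervised(s3, lags = 1L)
  expect_identical(unname(ds1$X), matrix(c(0.1, 0.2), 2, 1))
  expect_identical(ds1$Y, c(0.2, 0.3))

  expect_warning(empty <- build_supervised(
    p_series("c", c(5, 10), c(0.1, 0.2), 5, smoothed = TRUE), 2L), "skipped")
  expect_identical(nrow(empty$X), 0L)
})

test_that("supervised rows satisfy count and alignment invariants on random series", {
  set.seed(6)
  for (i in 1:50) {
    lags <- sample(1:5, 1)
    n <- sample((lags + 1):60, 1)
    p <- runif(n)
    s <- p_series("r", seq_len(n) * 5, p, 5, smoothed = TRUE)
    ds <- build_supervised(s, lags)
    expect_identical(nrow(ds$X), n - lags)
    # last X column is the value immediately preceding each target
    expect_identical(ds$X[, lags], p[lags:(n - 1)])
    # splitting rows reconstructs the series
    expect_identical(c(ds$X[1, ], ds$Y), p)
  }
})

test_that("concatenation preserves counts, lags, and stay provenance", {
  sA <- p_series("A", 1:5 * 5, runif(5), 5, smoothed = TRUE)
  sB <- p_series("B", 1:6 * 5, runif(6), 5, smoothed = TRUE)
  pooled <- concat_training(list(build_supervised(sA), build_supervised(sB)))
  expect_identical(nrow(pooled$X), 3L + 4L)
  expect_identical(pooled$stay_boundaries$stay_id, c("A", "B"))
  # no window spans two stays: every row's values come from its own stay
  for (r in seq_len(nrow(pooled$X))) {
    src <- if (pooled$stay_id[r] == "A") sA$p else sB$p
    expect_true(all(c(pooled$X[r, ], pooled$Y[r]) %in% src))
  }
  single <- concat_training(list(build_supervised(sA)))
  expect_identical(single$X, build_supervised(sA)$X)
  bad <- list(build_supervised(sA, 1L), build_supervised(sB, 2L))
  expect_error(concat_training(bad), "mixed lag")
})

test_that("the cohort pipeline orders transform, smooth, downsample correctly", {
  cohort <- generate_cohort(cohort_config(n_stays = 4, seed = 31))
  p5 <- preprocess_cohort(cohort, horizon_minutes = 5)
  p30 <- preprocess_cohort(cohort, horizon_minutes = 30)
  expect_true(all(vapply(p5$series, `[[`, 0, "interval_minutes") == 5))
  expect_true(all(vapply(p30$series, `[[`, 0, "interval_minutes") == 30))
  # 30-min series is the decimation of the smoothed 5-min series
  s5 <- p5$series[[1]]
  s30 <- p30$series[[1]]
  expect_identical(s30$p, s5$p[seq(1, length(s5$p), by = 6)])
  expect_true(all(vapply(p5$series, function(s) all(s$p >= 0 & s$p < 1), TRUE)))
})
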