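fr <- function(p_true, p_pred, id = "s1") {
  data.frame(stay_id = id, time_min = seq_along(p_true) * 5,
             p_true = p_true, p_pred = p_pred, stringsAsFactors = FALSE)
}
# transformed values for handy SpO2 levels
pv <- function(spo2) transform_spo2(spo2)

test_that("hypoxemia labels follow the strict 92% threshold", {
  expect_identical(classify_hypoxemia(pv(c(95, 92, 91, 75))),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(classify_hypoxemia(pv(rep(100, 5)))))
  expect_true(classify_hypoxemia(pv(92), include_boundary = TRUE))
  set.seed(20)
  spo2 <- runif(1e4, 0, 100)
  expect_identical(classify_hypoxemia(pv(spo2)), spo2 < 92)
})

test_that("per-stay metrics match the direct counting oracle", {
  # truth H,H,N,N vs predicted H,N,N,N
  m <- stay_metrics(fr(pv(c(90, 89, 96, 97)), pv(c(91, 93, 95, 98))))
  expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(1L, 0L, 2L, 1L))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$ppv, 1.0)
  expect_equal(m$accuracy, 0.75)
})

test_that("undefined metrics are NA exactly under the stated conditions", {
  # no true and no predicted events: sensitivity and PPV undefined
  m <- stay_metrics(fr(pv(c(97, 98, 96)), pv(c(96, 97, 98))))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_equal(m$specificity, 1.0)
  # all true events: specificity undefined
  m2 <- stay_metrics(fr(pv(c(85, 86, 84)), pv(c(85, 88, 85))))
  expect_true(is.na(m2$specificity))
  expect_false(is.na(m2$sensitivity))
  # constant true series: correlation undefined
  m3 <- stay_metrics(fr(rep(0.3, 5), c(0.3, 0.31, 0.29, 0.3, 0.32)))
  expect_true(is.na(m3$pearson_r))
  expect_error(stay_metrics(data.frame(stay_id = character(0),
                                       p_true = numeric(0),
                                       p_pred = numeric(0))), "empty")
})

test_that("a perfect forecast yields accuracy 1, MSE 0 and correlation 1", {
  p <- pv(c(97, 95, 90, 88, 93, 97))
  m <- stay_metrics(fr(p, p))
  expect_equal(m$accuracy, 1)
  expect_equal(m$mse, 0)
  expect_equal(m$pearson_r, 1)
})

test_that("pooled counts are additive and conserve the timepoint total", {
  a <- fr(pv(c(90, 96, 97, 98)), pv(c(91, 96, 97, 98)), "a")   # (1,0,3,0)
  b <- fr(pv(c(90, 96, 97, 98)), pv(c(95, 90, 97, 98)), "b")   # (0,1,2,1)
  mets <- cohort_metrics(rbind(a, b))
  pooled <- aggregate_confusion(mets)
  expect_identical(c(pooled$tp, pooled$fp, pooled$tn, pooled$fn), c(1L, 1L, 5L, 1L))
  expect_identical(pooled$n, 8L)

  single <- aggregate_confusion(mets[1, ])
  expect_equal(single$accuracy, mets$accuracy[1])
})

test_that("pooled rates equal a brute-force flatten-and-count oracle", {
  set.seed(21)
  frames <- lapply(1:6, function(i) {
    n <- sample(30:80, 1)
    truth <- runif(n, 0.3, 0.8)
    fr(truth, pmin(pmax(truth + rnorm(n, 0, 0.08), 0), 0.99), paste0("s", i))
  })
  pooled_frame <- do.call(rbind, frames)
  pooled <- aggregate_confusion(cohort_metrics(pooled_frame))
  lt <- classify_hypoxemia(pooled_frame$p_true)
  lp <- classify_hypoxemia(pooled_frame$p_pred)
  expect_identical(pooled$tp, sum(lt & lp))
  expect_identical(pooled$fp, sum(!lt & lp))
  expect_identical(pooled$tn, sum(!lt & !lp))
  expect_identical(pooled$fn, sum(lt & !lp))
  expect_equal(pooled$false_positive_rate, sum(!lt & lp) / sum(!lt))
  expect_equal(pooled$false_negative_rate, sum(lt & !lp) / sum(lt))
  expect_identical(pooled$n, nrow(pooled_frame))
})

test_that("cohort summaries use Tukey whiskers and exclude undefined values", {
  mets <- data.frame(stay_id = letters[1:4], tp = 1, fp = 0, tn = 1, fn = 0,
                     accuracy = c(0, 1, 0.5, 0.5),
                     sensitivity = c(NA, NA, 0.5, 0.7),
                     specificity = 1, ppv = 1, mse = 0.001,
                     pearson_r = c(0.9, 0.95, NA, 0.99))
  s <- summarize_cohort(mets)
  acc <- s[s$metric == "accuracy", ]
  expect_equal(acc$mean, 0.5)
  sens <- s[s$metric == "sensitivity", ]
  expect_identical(sens$n_undefined, 2L)
  expect_identical(sens$n, 2L)

  same <- summarize_cohort(data.frame(accuracy = rep(0.8, 6)), metrics = "accuracy")
  expect_equal(same$q1, same$median)
  expect_equal(same$median, same$q3)

  two <- summarize_cohort(data.frame(accuracy = c(0, 1)), metrics = "accuracy")
  expect_equal(two$mean, 0.5)

  set.seed(22)
  v <- runif(50)
  s2 <- summarize_cohort(data.frame(mse = v), metrics = "mse")
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_equal(s2$whisker_hi, q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(s2$whisker_lo, q[1] - 1.5 * (q[2] - q[1]))
})

test_that("the sensitivity subgroup comparison reproduces Welch's formula", {
  mk <- function(sens, events) {
    data.frame(stay_id = seq_along(sens), tp = round(sens * events),
               fp = 0, tn = 10, fn = events - round(sens * events),
               accuracy = 1, sensitivity = sens, specificity = 1, ppv = 1,
               mse = 0, pearson_r = 1)
  }
  # identical constant groups: t = 0, p = 1
  m <- mk(c(0.2, 0.3, 0.8, 0.9), 10)
  r <- sensitivity_subgroup_test(m, event_counts = rep(5, 4))
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)

  # clearly separated event counts: p < 0.01
  m2 <- mk(c(0.1, 0.2, 0.3, 0.9, 0.8, 0.95), 100)
  r2 <- sensitivity_subgroup_test(m2, event_counts = c(0, 0, 1, 50, 60, 70))
  expect_lt(r2$p_value, 0.01)

  # textbook Welch formula on random data
  set.seed(23)
  lo <- rpois(8, 4)
  hi <- rpois(9, 30)
  m3 <- mk(c(runif(8, 0, 0.49), runif(9, 0.5, 1)), 100)
  r3 <- sensitivity_subgroup_test(m3, event_counts = c(lo, hi))
  se2 <- var(lo) / 8 + var(hi) / 9
  t_hand <- (mean(lo) - mean(hi)) / sqrt(se2)
  df_hand <- se2^2 / ((var(lo) / 8)^2 / 7 + (var(hi) / 9)^2 / 8)
  expect_equal(r3$t, t_hand)
  expect_equal(r3$df, df_hand)
  expect_equal(r3$p_value, 2 * pt(-abs(t_hand), df_hand))

  # singleton subgroup: not computable
  r4 <- sensitivity_subgroup_test(mk(c(0.1, 0.9, 0.8), 10),
                                  event_counts = c(1, 5, 6))
  expect_false(r4$computable)
})

test_that("the chi-squared independence test matches the Pearson formula", {
  prop <- matrix(c(10, 20, 30, 60), 2, 2)  # proportional rows
  r <- ventilation_chisq(prop)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  tab <- matrix(c(10, 50, 90, 50), 2, 2)   # [[10,90],[50,50]]
  r2 <- ventilation_chisq(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r2$statistic, sum((tab - expected)^2 / expected))
  expect_equal(r2$df, 1)

  # invariant to swapping both rows and columns
  r3 <- ventilation_chisq(tab[2:1, 2:1])
  expect_equal(r3$statistic, r2$statistic)

  expect_error(ventilation_chisq(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})
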