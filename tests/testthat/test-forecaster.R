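test_that("a constant target is learned to near-zero validation MSE", {
  set.seed(30)
  X <- matrix(runif(600, 0.2, 0.4), 300, 2)
  ds <- swiftr:::supervised_set(2L, X, rep(0.3, 300), rep("s1", 300), seq_len(300))
  fit <- swift(ds, tiny_swift_config(epochs = 20L, seed = 3))
  expect_lt(fit$history$val_loss[fit$best_epoch], 1e-4)
})

test_that("training is deterministic given the seed", {
  ds <- recurrence_supervised(20, 12, 51)
  cfg <- tiny_swift_config(epochs = 5L, seed = 12)
  a <- swift(ds, cfg)
  b <- swift(ds, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$net$par, b$net$par)
  expect_identical(a$best_epoch, b$best_epoch)
})

test_that("best-epoch weights are restored, not final-epoch weights", {
  ds <- recurrence_supervised(30, 12, 52)
  fit <- swift(ds, tiny_swift_config(epochs = 40L, seed = 5), keep_final = TRUE)
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
  expect_lte(fit$history$val_loss[fit$best_epoch], min(fit$history$val_loss))
  # when the best epoch is not the last, the restored weights differ from
  # the final-epoch weights
  if (fit$best_epoch < nrow(fit$history)) {
    expect_false(identical(fit$net$par, fit$final_net$par))
  }
})

test_that("the forecaster learns a noiseless lag-2 linear recurrence", {
  train <- recurrence_supervised(150, 14, 11)
  test_series <- make_recurrence_series(40, 14, 12)
  fit <- swift(train, tiny_swift_config(epochs = 80L, seed = 7,
                                        lstm_widths = c(16L, 8L)))
  pred <- predict(fit, test_series)
  mse <- mean((pred$p_pred - pred$p_true)^2)
  pers <- persistence_forecast(test_series)
  pers_mse <- mean((pers$p_pred - pers$p_true)^2)
  expect_lt(mse, 1e-4)
  expect_lt(mse, 0.1 * pers_mse)
})

test_that("series prediction is aligned and bounded", {
  ds <- recurrence_supervised(10, 12, 54)
  fit <- swift(ds, tiny_swift_config(epochs = 5L, seed = 9))
  s <- make_recurrence_series(1, 20, 55)[[1]]
  fr <- predict(fit, s)
  expect_identical(nrow(fr), length(s$p) - 2L)
  expect_identical(fr$p_true, s$p[3:20])
  expect_true(all(is.finite(fr$p_pred)))
  expect_true(all(fr$p_pred >= 0 & fr$p_pred < 1))

  short <- p_series("tiny", c(5, 10), c(0.1, 0.2), 5, smoothed = TRUE)
  expect_warning(empty <- predict(fit, short), "too short")
  expect_identical(nrow(empty), 0L)

  s30 <- p_series("wrong", c(30, 60, 90), c(0.1, 0.2, 0.3), 30, smoothed = TRUE)
  expect_error(predict(fit, s30), "horizon")
})

test_that("model files round-trip exactly and reject foreign files", {
  ds <- recurrence_supervised(10, 12, 56)
  fit <- swift(ds, tiny_swift_config(epochs = 4L, seed = 13))
  path <- withr::local_tempfile(fileext = ".json")
  write_swift(fit, path)
  back <- read_swift(path)
  probe <- make_recurrence_series(1, 100, 57)[[1]]
  expect_equal(predict(back, probe)$p_pred, predict(fit, probe)$p_pred,
               tolerance = 1e-12)
  expect_identical(unclass(back$config), unclass(fit$config))
  expect_identical(back$best_epoch, fit$best_epoch)

  txt <- readLines(path)
  writeLines(gsub('"version":1', '"version":99', txt, fixed = TRUE), path)
  expect_error(read_swift(path), "version tag|format")
})

test_that("cross-validation selects by mean fold MSE and records the grid", {
  ds <- recurrence_supervised(30, 12, 58)
  one <- data.frame(architecture = "shallow", learning_rate = 0.01)
  cv1 <- swift_cv(ds, grid = one, config = tiny_swift_config(epochs = 3L, seed = 15),
                  widths = list(shallow = c(8L, 4L)))
  expect_identical(nrow(cv1$grid), 1L)
  expect_identical(cv1$selected$learning_rate, 0.01)
  expect_equal(cv1$mean_mse, rowMeans(cv1$fold_mse))
  expect_identical(dim(cv1$fold_mse), c(1L, 3L))
  expect_error(swift_cv(ds, folds = 1L), "at least 2")
})

test_that("an aggressive learning rate does not beat 0.001 at full shallow width", {
  # Stochastic check at the real architecture scale (256/16 units) with a
  # reduced epoch budget, fixed seed; noisy synthetic cohort data.
  prep <- small_prepped_cohort(n_stays = 10L, seed = 17L)
  ds <- concat_training(lapply(prep$series, build_supervised))
  grid <- data.frame(architecture = "shallow", learning_rate = c(0.001, 0.1))
  cv <- swift_cv(ds, grid = grid,
                 config = swift_config(epochs = 5L, batch_size = 256L, seed = 9))
  expect_gte(cv$mean_mse[2], cv$mean_mse[1])
})
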