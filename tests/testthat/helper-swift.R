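# Shared fixtures, all generated in code.

# Noiseless lag-2 linear recurrence x_t = a*x_{t-1} + b*x_{t-2}, one p_series
# per random start pair. Values stay inside the transform range.
make_recurrence_series <- function(n_seq, len, seed, a = 0.6, b = 0.4) {
  set.seed(seed)
  lapply(seq_len(n_seq), function(i) {
    x <- numeric(len)
    x[1:2] <- runif(2, 0.05, 0.95)
    for (t in 3:len) x[t] <- a * x[t - 1] + b * x[t - 2]
    p_series(sprintf("rec_%03d", i), seq_len(len) * 5, x,
             interval_minutes = 5, smoothed = TRUE)
  })
}

recurrence_supervised <- function(n_seq, len, seed, lags = 2L) {
  concat_training(lapply(make_recurrence_series(n_seq, len, seed),
                         build_supervised, lags = lags))
}

# Reduced-capacity forecaster config for fast tests.
tiny_swift_config <- function(epochs = 30L, seed = 7L, lstm_widths = c(8L, 4L), ...) {
  swift_config(lstm_widths = lstm_widths, epochs = epochs, batch_size = 64L,
               learning_rate = 0.01, dropout = 0, seed = seed, ...)
}

# A small preprocessed synthetic cohort, reused across tests.
small_prepped_cohort <- function(n_stays = 8L, seed = 17L) {
  cohort <- generate_cohort(cohort_config(n_stays = n_stays, seed = seed))
  preprocess_cohort(cohort)
}

# Stay with a given number of 5-minute points, constant SpO2.
flat_stay <- function(n, stay_id = "flat", spo2 = 97) {
  swiftr:::stay_series(stay_id, seq(0, by = 5, length.out = n), rep(spo2, n),
                       interval = 5)
}

make_stay <- function(time_min, spo2, stay_id = "s1", interval = NULL) {
  swiftr:::stay_series(stay_id, time_min, spo2, interval = interval)
}

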