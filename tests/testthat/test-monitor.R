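test_that("threshold calibration is the nearest-rank quantile", {
  expect_equal(calibrate_threshold(c(1, 2, 3, 4, 5), 1.0), 5)
  expect_equal(calibrate_threshold(c(1, 2, 3, 4, 5), 0.8), 4)
  expect_equal(calibrate_threshold(rep(7, 10), 0.3), 7)
  expect_equal(calibrate_threshold(rep(7, 10), 0.99), 7)
  # order must not matter
  expect_equal(calibrate_threshold(c(5, 1, 4, 2, 3), 0.8), 4)
  expect_error(calibrate_threshold(numeric(0)), "empty")
  expect_error(calibrate_threshold(1:5, quantile = 0),
               class = "gruae_config_error")
  # quantile sanity: exceedance fraction on the calibration data itself
  set.seed(20)
  x <- rexp(1000)
  for (q in c(0.9, 0.995)) {
    thr <- calibrate_threshold(x, q)
    expect_lte(mean(x > thr), 1 - q + 1 / length(x))
  }
})

# a deliberately mis-reconstructing model: all-zero parameters output 0.5,
# so the loss at each hour is a deterministic function of the input alone
zero_model <- function() {
  p <- gru_ae_params(2L, c(4L, 2L, 4L), seed = 1)
  for (k in 1:3) for (nm in c("Wu", "Uu", "Wr", "Ur", "Wc", "Uc"))
    p$layers[[k]][[nm]][] <- 0
  p$Wy[] <- 0; p$by <- c(0, 0)
  structure(list(params = p, loss_history = numeric(0),
                 config = train_config(epochs = 1L)),
            class = "gru_ae_model")
}

test_that("monitor emits alarms exactly at transitions above threshold", {
  ser <- vital_series(3L, "F", 40L, rep(36.6, 48), rep(72, 48))
  # inflate two separated hours so their loss stands out
  ser$temperature_c[c(10, 30)] <- 39.5
  nz <- structure(list(min = c(36, 60), max = c(38, 90),
                       target_low = 0.1, target_high = 0.9),
                  class = "vital_normalizer")
  m <- zero_model()
  losses <- monitor_stream(ser, monitor_config(m, nz, 1e9))$losses$loss_t
  thr <- sort(losses, decreasing = TRUE)[3]  # exactly 2 hours exceed
  res <- monitor_stream(ser, monitor_config(m, nz, thr))
  expect_equal(res$alarms$hour_index, c(10L, 30L))
  expect_true(all(res$alarms$loss > thr))
  expect_equal(sum(res$verdicts == "unhealthy"), 2L)
  expect_equal(subject_verdict(res$verdicts), "unhealthy")

  # all losses below threshold: no alarms, all healthy
  calm <- monitor_stream(ser, monitor_config(m, nz, max(losses) * 1.01))
  expect_equal(nrow(calm$alarms), 0L)
  expect_true(all(calm$verdicts == "healthy"))
  expect_equal(subject_verdict(calm$verdicts), "healthy")
})

test_that("raising the threshold never increases the number of alarms", {
  ser <- vital_series(1L, "M", 20L,
                      36.6 + 0.4 * sin(2 * pi * ((0:95) - 8) / 24),
                      72 + 8 * sin(2 * pi * ((0:95) - 8) / 24))
  set.seed(2)
  ser$temperature_c <- ser$temperature_c + rnorm(96, 0, 0.2)
  nz <- structure(list(min = c(35.5, 60), max = c(38, 85),
                       target_low = 0.1, target_high = 0.9),
                  class = "vital_normalizer")
  m <- zero_model()
  losses <- monitor_stream(ser, monitor_config(m, nz, 1e9))$losses$loss_t
  thresholds <- quantile(losses, c(0.1, 0.3, 0.5, 0.7, 0.9, 1))
  n_alarmed_hours <- sapply(thresholds, function(th)
    sum(monitor_stream(ser, monitor_config(m, nz, th))$verdicts == "unhealthy"))
  expect_true(all(diff(n_alarmed_hours) <= 0))
  # and with a run-length requirement, hours in alarm remain monotone
  n_k3 <- sapply(thresholds, function(th)
    sum(monitor_stream(ser, monitor_config(m, nz, th,
                                           min_consecutive = 3L))$verdicts == "unhealthy"))
  expect_true(all(diff(n_k3) <= 0))
})

test_that("hour-by-hour streaming equals one whole-sequence pass", {
  coh <- tiny_cohort(seed = 12)
  sp <- chronological_split(coh, 1L)
  nz <- fit_normalizer(sp$train)
  win <- cohort_windows(sp$train, nz, window_length = 48L)
  m <- train_gru_ae(win, train_config(epochs = 10L, seed = 2),
                    hidden_sizes = c(6L, 3L, 6L))
  ser <- cohort_series(sp$test, coh$episodes$subject_id[1])
  thr <- 0.01
  whole <- monitor_stream(ser, monitor_config(m, nz, thr))
  # feed the same series one hour at a time, carrying states manually
  x <- apply_normalizer(nz, ser)
  states <- NULL
  losses <- numeric(nrow(x))
  for (t in seq_len(nrow(x))) {
    fwd <- gru_ae_forward(x[t, , drop = FALSE], m$params, states)
    states <- fwd$states
    losses[t] <- reconstruction_loss(x[t, , drop = FALSE], fwd$y)$total
  }
  expect_equal(losses, whole$losses$loss_t, tolerance = 1e-12)
  expect_equal(ifelse(losses > thr, "unhealthy", "healthy"), whole$verdicts)
})

test_that("min_consecutive suppresses short excursions", {
  exceed <- c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(gruae:::qualifying_runs(exceed, 1L), exceed)
  expect_equal(gruae:::qualifying_runs(exceed, 3L),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(gruae:::qualifying_runs(exceed, 4L), rep(FALSE, 9))
})

test_that("a trained monitor alarms inside a true fever episode", {
  coh <- generate_cohort(cohort_config(
    n_subjects = 6L, n_weeks = 3L, n_unhealthy_subjects = 2L, n_male = 3L,
    episode_spec = episode_spec(duration_range = c(8L, 12L))), seed = 77)
  sp <- chronological_split(coh, 2L)
  nz <- fit_normalizer(sp$train)
  win <- cohort_windows(sp$train, nz, window_length = 168L)
  m <- train_gru_ae(win, train_config(epochs = 80L, seed = 7),
                    hidden_sizes = c(16L, 8L, 16L))
  thr <- calibrate_threshold(as.numeric(
    gruae:::cohort_loss_matrix(m, sp$train, nz)), 0.995)
  mc <- monitor_config(m, nz, thr)
  sid <- sp$test$episodes$subject_id[1]
  epi <- sp$test$episodes[sp$test$episodes$subject_id == sid, ]
  res <- monitor_stream(cohort_series(sp$test, sid), mc)
  expect_gt(nrow(res$alarms), 0L)
  expect_true(any(res$alarms$hour_index >= epi$start_hour &
                    res$alarms$hour_index <= epi$end_hour))
})

test_that("subject verdicts partition the cohort", {
  expect_equal(subject_verdict(c("healthy", "healthy")), "healthy")
  expect_equal(subject_verdict(c("healthy", "unhealthy")), "unhealthy")
  expect_error(subject_verdict(character(0)), "empty")
})
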