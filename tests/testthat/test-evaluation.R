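test_that("mae and rmse follow their definitions", {
  y <- c(1, 2, 3)
  expect_equal(mae_rmse(y, y), c(mae = 0, rmse = 0))
  # equal-magnitude errors: RMSE == MAE
  r <- mae_rmse(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(unname(r["mae"]), 1)
  expect_equal(unname(r["rmse"]), 1)
  r2 <- mae_rmse(c(0, 2), c(0, 0))
  expect_equal(unname(r2["mae"]), 1)
  expect_equal(unname(r2["rmse"]), sqrt(2))
  expect_error(mae_rmse(numeric(0), numeric(0)), "empty")
})

test_that("rmse >= mae on randomized inputs", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    r <- mae_rmse(rnorm(n, sd = runif(1, 0.1, 5)), rnorm(n))
    expect_gte(r[["rmse"]], r[["mae"]] - 1e-12)
  }
})

test_that("confusion counts use the healthy-as-positive convention", {
  r <- confusion(c("healthy", "healthy", "unhealthy", "unhealthy"),
                 c("healthy", "unhealthy", "healthy", "unhealthy"))
  expect_equal(r$counts, c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(r$tpr, 0.5)
  expect_equal(r$fpr, 0.5)
  expect_equal(r$accuracy, 0.5)

  perfect <- confusion(c("healthy", "unhealthy"), c("healthy", "unhealthy"))
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$accuracy, 1)

  # undefined ratios surface as NA with a warning, never silently 0
  expect_warning(r1 <- confusion(c("healthy", "healthy"),
                                 c("healthy", "unhealthy")), "FPR")
  expect_true(is.na(r1$fpr))
  expect_equal(r1$tpr, 0.5)
})

test_that("printed-count accuracy arithmetic reproduces", {
  # 1924 of 2000 subjects correct -> 96.2%
  actual <- rep(c("healthy", "unhealthy"), c(1387, 613))
  predicted <- actual
  wrong_h <- seq_len(44)          # 44 healthy misread
  wrong_u <- 1387 + seq_len(32)   # 32 unhealthy misread -> 581 correct
  predicted[wrong_h] <- "unhealthy"
  predicted[wrong_u] <- "healthy"
  r <- confusion(actual, predicted)
  expect_equal(sum(r$counts), 2000)
  expect_equal(unname(r$counts["TP"] + r$counts["TN"]), 1924)
  expect_equal(r$accuracy, 0.962)
  expect_equal(unname(r$counts["TN"]) / 613, 581 / 613)
  expect_equal(round(100 * r$counts[["TN"]] / 613, 1), 94.8)
})

test_that("rank-formula AUC handles separation, ties, and hand example", {
  # perfect separation on healthiness scores (low loss = healthy)
  expect_equal(roc_and_auc(c(0.1, 0.2, 0.8, 0.9),
                           c("healthy", "healthy", "unhealthy", "unhealthy"))$auc,
               1)
  # all scores identical: AUC 1/2 by average ranks
  expect_equal(roc_and_auc(rep(0.5, 6),
                           rep(c("healthy", "unhealthy"), 3))$auc, 0.5)
  # healthiness scores healthy {0.8, 0.3}, unhealthy {0.5, 0.1}:
  # ranks 4, 2 -> AUC = (6 - 3)/4 = 0.75
  r <- roc_and_auc(-c(0.8, 0.3, 0.5, 0.1),
                   c("healthy", "healthy", "unhealthy", "unhealthy"))
  expect_equal(r$auc, 0.75)
  expect_error(roc_and_auc(1:3, rep("healthy", 3)), "unhealthy")
  expect_error(roc_and_auc(1:3, rep("unhealthy", 3)), "healthy")
})

test_that("rank AUC equals the exhaustive pairwise oracle with tie-halving", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    healthy <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(healthy)) healthy[1] <- FALSE
    if (!any(healthy)) healthy[1] <- TRUE
    # coarse grid forces plenty of ties
    losses <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    got <- roc_and_auc(losses, ifelse(healthy, "healthy", "unhealthy"))
    expect_equal(got$auc, pairwise_auc(losses, healthy), tolerance = 1e-12)
  }
})

test_that("ROC endpoints and trapezoidal area agree with the rank formula", {
  set.seed(66)
  for (i in 1:10) {
    n <- sample(10:120, 1)
    healthy <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    losses <- round(rexp(n), 2)
    r <- roc_and_auc(losses, ifelse(healthy, "healthy", "unhealthy"))
    expect_equal(r$roc$fpr[1], 0)
    expect_equal(r$roc$tpr[1], 0)
    expect_equal(r$roc$fpr[nrow(r$roc)], 1)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
    expect_equal(gruae:::roc_trapezoid(r$roc), r$auc, tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone transforms of the score", {
  set.seed(8)
  losses <- rexp(40)
  healthy <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  healthy[1:2] <- c(TRUE, FALSE)
  lab <- ifelse(healthy, "healthy", "unhealthy")
  base <- roc_and_auc(losses, lab)$auc
  expect_equal(roc_and_auc(losses^3, lab)$auc, base)
  expect_equal(roc_and_auc(exp(losses), lab)$auc, base)
  expect_equal(roc_and_auc(10 + 2 * losses, lab)$auc, base)
})

test_that("paired evaluation reports consistent structure", {
  coh <- generate_cohort(cohort_config(
    n_subjects = 6L, n_weeks = 3L, n_unhealthy_subjects = 2L, n_male = 3L,
    episode_spec = episode_spec(duration_range = c(8L, 12L))), seed = 91)
  sp <- chronological_split(coh, 2L)
  nz <- fit_normalizer(sp$train)
  win <- cohort_windows(sp$train, nz, window_length = 168L)
  cfg <- train_config(epochs = 40L, seed = 9)
  gm <- train_gru_ae(win, cfg, hidden_sizes = c(8L, 4L, 8L))
  am <- train_ae(win, cfg, hidden_sizes = c(8L, 4L, 8L))
  gthr <- calibrate_threshold(as.numeric(gruae:::cohort_loss_matrix(gm, sp$train, nz)))
  athr <- calibrate_threshold(as.numeric(gruae:::cohort_loss_matrix(am, sp$train, nz)))
  rep <- evaluate_models(sp$test, monitor_config(gm, nz, gthr),
                         monitor_config(am, nz, athr))
  for (m in rep$models) {
    expect_equal(nrow(m$per_subject), 6L)
    expect_equal(m$n_subjects_with_auc, 2L)  # only episodic subjects have both classes
    expect_equal(sum(m$subject_confusion$counts), 6)
    expect_true(m$pooled_auc >= 0 && m$pooled_auc <= 1)
  }
  # identical model on both slots -> identical reports
  rep2 <- evaluate_models(sp$test, monitor_config(gm, nz, gthr),
                          monitor_config(gm, nz, gthr))
  expect_identical(rep2$models$gru_ae, rep2$models$ae)
})
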