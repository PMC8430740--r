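#' Mean absolute error and root mean squared error
#'
#' `MAE = mean(|y - yhat|)`, `RMSE = sqrt(mean((y - yhat)^2))`. RMSE is
#' always at least MAE; equality means all errors have the same magnitude,
#' so the ratio RMSE/MAE diagnoses the spread of the individual errors.
#'
#' @param y,yhat numeric vectors of equal positive length.
#' @return Named numeric vector `c(mae = ..., rmse = ...)`.
#' @export
mae_rmse <- function(y, yhat) {
  if (length(y) == 0L) stop("mae_rmse: empty input")
  if (length(y) != length(yhat))
    stop_format("mae_rmse: lengths differ (", length(y), " vs ",
                length(yhat), ")")
  e <- y - yhat
  c(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

as_health_label <- function(x) {
  if (is.logical(x)) return(ifelse(x, "healthy", "unhealthy"))
  if (is.numeric(x)) return(ifelse(x > 0, "healthy", "unhealthy"))
  x <- as.character(x)
  bad <- setdiff(unique(x), c("healthy", "unhealthy"))
  if (length(bad) > 0)
    stop_format("labels must be 'healthy'/'unhealthy' (or logical/0-1); got ",
                paste(bad, collapse = ", "))
  x
}

#' Confusion counts and rates under the healthy-as-positive convention
#'
#' Healthy is the positive class: TP = predicted healthy and actually
#' healthy, TN = predicted unhealthy and actually unhealthy, FP = predicted
#' healthy but actually unhealthy, FN = predicted unhealthy but actually
#' healthy. Then `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)` and
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`. A ratio with an empty denominator
#' is reported as `NA` with a warning, never silently zero.
#'
#' @param actual,predicted equal-length label vectors
#'   (`"healthy"`/`"unhealthy"`, logical healthy, or 0/1 with 1 = healthy).
#' @return List with `counts` (named TP/TN/FP/FN), `tpr`, `fpr`, `accuracy`.
#' @export
confusion <- function(actual, predicted) {
  actual <- as_health_label(actual)
  predicted <- as_health_label(predicted)
  if (length(actual) != length(predicted))
    stop_format("confusion: lengths differ")
  tp <- sum(predicted == "healthy" & actual == "healthy")
  tn <- sum(predicted == "unhealthy" & actual == "unhealthy")
  fp <- sum(predicted == "healthy" & actual == "unhealthy")
  fn <- sum(predicted == "unhealthy" & actual == "healthy")
  rate <- function(num, den, what) {
    if (den == 0L) {
      warning("confusion: ", what, " undefined (empty denominator)",
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  list(counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
       tpr = rate(tp, tp + fn, "TPR"),
       fpr = rate(fp, fp + tn, "FPR"),
       accuracy = rate(tp + tn, tp + tn + fp + fn, "accuracy"))
}

#' ROC curve and rank-statistic AUC from anomaly losses
#'
#' Scores are reconstruction losses (higher = more anomalous); the
#' healthiness score is their negation, keeping healthy as the positive
#' class. The ROC sweeps the loss threshold over all distinct values
#' (an hour is predicted healthy when its loss is at or below the
#' threshold). AUC uses the rank statistic
#' `AUC = (sum of healthy ranks - M(M+1)/2) / (M * N)` with M healthy and
#' N unhealthy units, ranking all units by ascending healthiness and
#' averaging tied ranks; this equals the probability that a random healthy
#' unit out-scores a random unhealthy one (ties counted half) and the
#' trapezoidal area under the swept ROC.
#'
#' @param losses numeric anomaly scores, one per unit.
#' @param actual matching labels (healthy positive).
#' @return List with `roc` (data frame fpr, tpr, threshold), `auc`,
#'   `n_healthy`, `n_unhealthy`.
#' @export
roc_and_auc <- function(losses, actual) {
  actual <- as_health_label(actual)
  if (length(losses) != length(actual))
    stop_format("roc_and_auc: lengths differ")
  pos <- actual == "healthy"
  if (!any(pos)) stop("roc_and_auc: no healthy (positive) units present")
  if (all(pos)) stop("roc_and_auc: no unhealthy (negative) units present")
  M <- sum(pos); N <- sum(!pos)

  healthiness <- -losses
  rk <- rank(healthiness, ties.method = "average")
  auc <- (sum(rk[pos]) - M * (M + 1) / 2) / (M * N)

  thr <- c(-Inf, sort(unique(losses)))
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred_healthy <- losses <= thr[i]
    tpr[i] <- sum(pred_healthy & pos) / M
    fpr[i] <- sum(pred_healthy & !pos) / N
  }
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc, n_healthy = M, n_unhealthy = N)
}

# Trapezoidal area under a swept ROC (used as an internal cross-check).
roc_trapezoid <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Side-by-side evaluation of the GRU-AE and the AE baseline
#'
#' Scores every test subject with both models, computes per-subject AUC
#' over the per-hour losses (only for subjects whose test window contains
#' both healthy and unhealthy hours; healthy-only subjects are counted
#' separately), pooled AUC over all test hours, and subject-level confusion
#' from the thresholded monitor (a subject is flagged unhealthy if any
#' monitored hour is unhealthy). Reported per model: mean per-subject AUC,
#' pooled AUC, overall subject accuracy, and accuracy on unhealthy subjects
#' (the fraction of truly unhealthy subjects correctly flagged).
#'
#' @param test_cohort the test `vital_cohort`.
#' @param gru_config,ae_config [monitor_config()]s for the two models.
#' @param warmup_cohort optional cohort (e.g. the tail training weeks) run
#'   through the GRU before scoring, so streaming states are warm at the
#'   test boundary.
#' @return An object of class `eval_report`.
#' @export
evaluate_models <- function(test_cohort, gru_config, ae_config,
                            warmup_cohort = NULL) {
  stopifnot(inherits(test_cohort, "vital_cohort"))
  configs <- list(gru_ae = gru_config, ae = ae_config)
  truth <- test_cohort$data$label
  ids <- test_cohort$subjects$subject_id
  n <- length(ids)
  Tn <- test_cohort$n_hours

  reports <- lapply(configs, function(cfg) {
    init <- NULL
    if (!is.null(warmup_cohort) && inherits(cfg$model, "gru_ae_model")) {
      wl <- cohort_loss_matrix(cfg$model, warmup_cohort, cfg$normalizer)
      init <- attr(wl, "states")
    }
    lm <- cohort_loss_matrix(cfg$model, test_cohort, cfg$normalizer, init)
    truth_m <- matrix(as.integer(truth == "healthy"), n, Tn, byrow = TRUE)

    per_subj <- data.frame(subject_id = ids, auc = NA_real_,
                           verdict = NA_character_)
    for (i in seq_len(n)) {
      lab <- truth_m[i, ]
      if (any(lab == 0L) && any(lab == 1L)) {
        per_subj$auc[i] <- roc_and_auc(lm[i, ], lab)$auc
      }
      exceed <- lm[i, ] > cfg$threshold
      unhealthy <- qualifying_runs(exceed, cfg$min_consecutive)
      per_subj$verdict[i] <- if (any(unhealthy)) "unhealthy" else "healthy"
    }
    actual_subject <- ifelse(ids %in% test_cohort$episodes$subject_id,
                             "unhealthy", "healthy")
    conf <- confusion(actual_subject, per_subj$verdict)
    acc_unhealthy <- if (sum(actual_subject == "unhealthy") > 0) {
      sum(per_subj$verdict == "unhealthy" &
            actual_subject == "unhealthy") /
        sum(actual_subject == "unhealthy")
    } else NA_real_

    pooled <- roc_and_auc(as.numeric(t(lm)), truth)
    list(per_subject = per_subj,
         mean_subject_auc = mean(per_subj$auc, na.rm = TRUE),
         n_subjects_with_auc = sum(!is.na(per_subj$auc)),
         pooled_auc = pooled$auc,
         subject_confusion = conf,
         subject_accuracy = conf$accuracy,
         accuracy_unhealthy = acc_unhealthy)
  })

  structure(list(models = reports, n_subjects = n, n_hours = Tn),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: %d subjects x %d test hours>\n",
              x$n_subjects, x$n_hours))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-6s mean subject AUC %.3f (n=%d) | pooled AUC %.3f | subject accuracy %.3f | accuracy on unhealthy %.3f\n",
                nm, m$mean_subject_auc, m$n_subjects_with_auc, m$pooled_auc,
                m$subject_accuracy, m$accuracy_unhealthy))
  }
  invisible(x)
}
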