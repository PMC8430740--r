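#' Calibrate an alarm threshold from healthy losses
#'
#' Nearest-rank quantile of the pooled healthy training losses: the
#' `ceiling(q * n)`-th order statistic. With the default q = 0.995 about
#' 0.5% of healthy training hours would exceed the threshold.
#'
#' @param losses numeric vector (or list of `loss_trace`s) of healthy
#'   reconstruction losses.
#' @param quantile calibration fraction in (0, 1].
#' @return The threshold (single number).
#' @export
calibrate_threshold <- function(losses, quantile = 0.995) {
  if (is.list(losses))
    losses <- unlist(lapply(losses, function(l)
      if (inherits(l, "loss_trace")) l$loss_t else l))
  losses <- as.numeric(losses)
  if (length(losses) == 0L)
    stop("calibrate_threshold: empty loss collection")
  if (quantile <= 0 || quantile > 1)
    stop_config("calibrate_threshold: quantile must be in (0, 1]")
  sort(losses)[ceiling(quantile * length(losses))]
}

#' Monitoring configuration
#'
#' Bundles a trained model, its training-time normalizer and the alarm
#' threshold applied to the per-hour reconstruction loss.
#'
#' @param model a `gru_ae_model` or `ae_model`.
#' @param normalizer the [fit_normalizer()] result fitted on training data.
#' @param threshold positive loss threshold (see [calibrate_threshold()]).
#' @param calibration_quantile the quantile used to derive `threshold`
#'   (metadata).
#' @param min_consecutive number of consecutive exceeding hours required
#'   before hours are deemed unhealthy; 1 alarms on any single exceeding
#'   hour, larger values suppress short spikes (e.g. exercise).
#' @return An object of class `monitor_config`.
#' @export
monitor_config <- function(model, normalizer, threshold,
                           calibration_quantile = 0.995,
                           min_consecutive = 1L) {
  if (threshold <= 0) stop_config("monitor_config: threshold must be > 0")
  if (min_consecutive < 1L)
    stop_config("monitor_config: min_consecutive must be >= 1")
  structure(list(model = model, normalizer = normalizer,
                 threshold = threshold,
                 calibration_quantile = calibration_quantile,
                 min_consecutive = as.integer(min_consecutive)),
            class = "monitor_config")
}

# Hours belonging to runs of >= k consecutive exceedances.
qualifying_runs <- function(exceed, k) {
  if (k <= 1L) return(exceed)
  r <- rle(exceed)
  r$values <- r$values & r$lengths >= k
  inverse.rle(r)
}

#' Stream one subject through the monitor
#'
#' Hour by hour: normalize the sample, advance the carried GRU hidden
#' states, reconstruct, compute the loss `Loss_t`, and compare to the
#' threshold. An hour's verdict is unhealthy when it belongs to a run of at
#' least `min_consecutive` exceeding hours; an alarm event is emitted at
#' each transition into the unhealthy state. Hidden states are never reset
#' within a subject's stream (and reset between subjects).
#'
#' @param series a [vital_series()].
#' @param config a [monitor_config()].
#' @param init_states optional GRU states carried from earlier data of the
#'   same subject (see [warmup_states()]); `NULL` starts from zero.
#' @return List with `losses` (a `loss_trace`), `alarms` (data frame
#'   subject_id, hour_index, loss, threshold), `verdicts` (per-hour
#'   `"healthy"`/`"unhealthy"`), and `states` (final GRU states).
#' @export
monitor_stream <- function(series, config, init_states = NULL) {
  stopifnot(inherits(series, "vital_series"), inherits(config, "monitor_config"))
  x <- apply_normalizer(config$normalizer, series)
  tr <- model_loss_trace(config$model, x, init_states)
  exceed <- tr$loss_t > config$threshold
  unhealthy <- qualifying_runs(exceed, config$min_consecutive)
  verdicts <- ifelse(unhealthy, "unhealthy", "healthy")
  onset <- which(unhealthy & !c(FALSE, unhealthy[-length(unhealthy)]))
  alarms <- data.frame(subject_id = rep(series$subject_id, length(onset)),
                       hour_index = series$hour_index[onset],
                       loss = tr$loss_t[onset],
                       threshold = rep(config$threshold, length(onset)))
  list(losses = structure(list(loss_t = tr$loss_t, total = sum(tr$loss_t)),
                          class = "loss_trace"),
       alarms = alarms, verdicts = verdicts, states = tr$states)
}

#' Aggregate per-hour verdicts into a subject-level verdict
#'
#' A subject is deemed unhealthy if at least one monitored hour is
#' unhealthy (noise robustness is delegated to `min_consecutive` in the
#' monitor).
#'
#' @param verdicts character vector of per-hour verdicts.
#' @return `"healthy"` or `"unhealthy"`.
#' @export
subject_verdict <- function(verdicts) {
  if (length(verdicts) == 0L) stop("subject_verdict: empty verdict vector")
  if (any(verdicts == "unhealthy")) "unhealthy" else "healthy"
}

#' Carry GRU states through a warm-up series
#'
#' Runs the model over `series` (e.g. the tail of the training period) and
#' returns the final hidden states, so that monitoring of the subsequent
#' test period starts from the subject's true streaming state instead of a
#' cold zero state.
#'
#' @param model a `gru_ae_model`.
#' @param series a [vital_series()].
#' @param normalizer the training-time normalizer.
#' @return List of three hidden-state vectors.
#' @export
warmup_states <- function(model, series, normalizer) {
  stopifnot(inherits(model, "gru_ae_model"))
  x <- apply_normalizer(normalizer, series)
  gru_ae_forward(x, model$params)$states
}
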