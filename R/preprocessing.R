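#' Chronological train/test split of a cohort
#'
#' Per subject, the first `train_weeks * 168` hours form the training
#' cohort and the remainder the test cohort, with test hour indices rebased
#' to start at 1 (so a 24-week cohort split at 20 weeks yields test hours
#' 1..672 per subject). Episode intervals are assigned to the half they
#' fall in and rebased likewise. No sample appears in both halves.
#'
#' @param cohort a `vital_cohort`.
#' @param train_weeks number of initial weeks in the training split.
#' @return A list with elements `train` and `test`, both `vital_cohort`s.
#' @export
chronological_split <- function(cohort, train_weeks = 20L) {
  stopifnot(inherits(cohort, "vital_cohort"))
  n_weeks <- cohort$n_hours / HOURS_PER_WEEK
  if (train_weeks < 1L || train_weeks >= n_weeks)
    stop_config("chronological_split: train_weeks (", train_weeks,
                ") must be in [1, n_weeks) = [1, ", n_weeks, ")")
  cut <- as.integer(train_weeks * HOURS_PER_WEEK)

  in_train <- cohort$data$hour_index <= cut
  train <- cohort
  train$data <- cohort$data[in_train, , drop = FALSE]
  rownames(train$data) <- NULL
  train$split <- "train"
  train$n_hours <- cut

  test <- cohort
  test$data <- cohort$data[!in_train, , drop = FALSE]
  test$data$hour_index <- test$data$hour_index - cut
  rownames(test$data) <- NULL
  test$split <- "test"
  test$n_hours <- cohort$n_hours - cut

  clip_episodes <- function(ep, lo, hi, shift) {
    keep <- ep$end_hour >= lo & ep$start_hour <= hi
    ep <- ep[keep, , drop = FALSE]
    ep$start_hour <- pmax(ep$start_hour, lo) - shift
    ep$end_hour <- pmin(ep$end_hour, hi) - shift
    rownames(ep) <- NULL
    ep
  }
  train$episodes <- clip_episodes(cohort$episodes, 1L, cut, 0L)
  test$episodes <- clip_episodes(cohort$episodes, cut + 1L, cohort$n_hours, cut)
  train$subjects$unhealthy <- train$subjects$subject_id %in% train$episodes$subject_id
  test$subjects$unhealthy <- test$subjects$subject_id %in% test$episodes$subject_id
  list(train = train, test = test)
}

#' Fit a per-channel min-max normalizer on training data
#'
#' Maps each channel's training range `[min, max]` affinely onto
#' `[target_low, target_high]`. The sigmoid output head of the autoencoders
#' bounds reconstructions to (0, 1), so raw degrees C / bpm must be scaled;
#' the 0.1/0.9 margins keep healthy data away from sigmoid saturation.
#' Test-set anomalies may map outside the target band and are deliberately
#' not clipped, since clipping would erase the anomaly signal.
#'
#' @param train a training `vital_cohort` (or a numeric matrix with one
#'   column per channel).
#' @param target_low,target_high target band bounds.
#' @return An object of class `vital_normalizer`.
#' @export
fit_normalizer <- function(train, target_low = 0.1, target_high = 0.9) {
  if (target_low >= target_high)
    stop_config("fit_normalizer: target_low must be < target_high")
  x <- if (inherits(train, "vital_cohort")) channel_matrix(train) else as.matrix(train)
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  if (any(maxs <= mins))
    stop_config("fit_normalizer: degenerate channel (constant on training ",
                "data): ", paste(colnames(x)[maxs <= mins], collapse = ", "))
  structure(list(min = mins, max = maxs,
                 target_low = target_low, target_high = target_high),
            class = "vital_normalizer")
}

# Samples of a cohort (or series) as an hours x channels matrix.
channel_matrix <- function(x) {
  if (inherits(x, "vital_cohort")) {
    cbind(temperature_c = x$data$temperature_c,
          heart_rate_bpm = x$data$heart_rate_bpm)
  } else if (inherits(x, "vital_series")) {
    cbind(temperature_c = x$temperature_c, heart_rate_bpm = x$heart_rate_bpm)
  } else {
    as.matrix(x)
  }
}

#' Apply (or invert) a fitted normalizer
#'
#' @param normalizer a [fit_normalizer()] result.
#' @param x numeric matrix (rows = hours, columns = channels), a
#'   `vital_series`, or a `vital_cohort`.
#' @param invert if `TRUE`, map from the target band back to signal units.
#' @return A numeric matrix of the same shape.
#' @export
apply_normalizer <- function(normalizer, x, invert = FALSE) {
  stopifnot(inherits(normalizer, "vital_normalizer"))
  m <- channel_matrix(x)
  if (ncol(m) != length(normalizer$min))
    stop_format("apply_normalizer: expected ", length(normalizer$min),
                " channels, got ", ncol(m))
  span <- normalizer$max - normalizer$min
  tspan <- normalizer$target_high - normalizer$target_low
  if (invert) {
    sweep(sweep(m, 2, normalizer$target_low) / tspan, 2, span, `*`) +
      matrix(normalizer$min, nrow(m), ncol(m), byrow = TRUE)
  } else {
    sweep(sweep(m, 2, normalizer$min) , 2, span, `/`) * tspan +
      normalizer$target_low
  }
}

#' Cut a series into fixed-length windows
#'
#' Produces `floor((T - L) / stride) + 1` windows of length `L` for a
#' series of length `T >= L`; each window records its origin (subject and
#' starting hour) for traceback.
#'
#' @param series a `vital_series`, or a numeric matrix (hours x channels).
#' @param window_length window length L in hours.
#' @param stride hop between consecutive window starts, in hours.
#' @param subject_id origin id used when `series` is a bare matrix.
#' @return An object of class `window_batch`: list with `windows` (array
#'   `n x L x channels`), `origin` (data frame subject_id, start_hour),
#'   `window_length`, `stride`.
#' @export
make_windows <- function(series, window_length = 24L, stride = window_length,
                         subject_id = NA_integer_) {
  m <- channel_matrix(series)
  if (inherits(series, "vital_series")) subject_id <- series$subject_id
  T_len <- nrow(m)
  L <- as.integer(window_length)
  stride <- as.integer(stride)
  if (L < 1L || stride < 1L)
    stop_config("make_windows: window_length and stride must be >= 1")
  if (T_len < L)
    stop_range("make_windows: series length ", T_len,
               " is shorter than window_length ", L)
  n_win <- (T_len - L) %/% stride + 1L
  starts <- (seq_len(n_win) - 1L) * stride + 1L
  w <- array(NA_real_, dim = c(n_win, L, ncol(m)))
  for (i in seq_len(n_win)) {
    w[i, , ] <- m[seq.int(starts[i], starts[i] + L - 1L), , drop = FALSE]
  }
  structure(list(windows = w,
                 origin = data.frame(subject_id = rep(subject_id, n_win),
                                     start_hour = starts),
                 window_length = L, stride = stride),
            class = "window_batch")
}

#' Normalized training windows for a whole cohort
#'
#' Applies a fitted normalizer to every subject's series and stacks the
#' resulting windows into one batch.
#'
#' @param cohort a `vital_cohort`.
#' @param normalizer a [fit_normalizer()] result.
#' @param window_length,stride as in [make_windows()]; the training default
#'   is one week (168 h) of hourly samples, so that the state distribution
#'   seen in training matches week-scale streaming at monitoring time.
#' @return A `window_batch` spanning all subjects.
#' @export
cohort_windows <- function(cohort, normalizer, window_length = 168L,
                           stride = window_length) {
  stopifnot(inherits(cohort, "vital_cohort"))
  ids <- cohort$subjects$subject_id
  parts <- lapply(ids, function(sid) {
    rows <- cohort$data$subject_id == sid
    m <- apply_normalizer(normalizer,
                          cbind(cohort$data$temperature_c[rows],
                                cohort$data$heart_rate_bpm[rows]))
    make_windows(m, window_length, stride, subject_id = sid)
  })
  windows <- do.call(abind1, lapply(parts, `[[`, "windows"))
  origin <- do.call(rbind, lapply(parts, `[[`, "origin"))
  structure(list(windows = windows, origin = origin,
                 window_length = as.integer(window_length),
                 stride = as.integer(stride)),
            class = "window_batch")
}

# rbind for 3-d arrays along the first dimension
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, dim = c(sum(vapply(parts, function(p) dim(p)[1], 0)),
                                 d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
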