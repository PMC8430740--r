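#' Configuration for a synthetic vital-sign cohort
#'
#' Describes the generative design of a monitored cohort: hourly bivariate
#' vital signs (body temperature in degrees Celsius, heart rate in beats per
#' minute) for `n_subjects` subjects over `n_weeks` weeks. Healthy signal =
#' subject-independent circadian sinusoid + Gaussian noise + occasional
#' short activity spikes (exercise; labeled healthy). A fixed number of
#' subjects additionally carry one fever episode with elevated temperature
#' and heart rate (labeled unhealthy), placed by default in the final test
#' weeks so that training data are healthy-only.
#'
#' The defaults reproduce the reference study design: 2000 subjects aged
#' 18-50 (978 male, 1022 female), 24 weeks of hourly sampling (4032 hours,
#' 8,064,000 samples in total), 613 subjects with health-issue episodes.
#'
#' @param n_subjects number of subjects.
#' @param n_weeks duration in weeks; each subject has `n_weeks * 168` hourly
#'   samples.
#' @param n_unhealthy_subjects number of subjects receiving exactly one
#'   injected episode.
#' @param n_male number of male subjects; the rest are female.
#' @param age_range integer range of ages (years), sampled uniformly.
#' @param healthy_temp_mean,healthy_temp_sd baseline body-temperature mean
#'   and hourly noise standard deviation (degrees C).
#' @param healthy_hr_mean,healthy_hr_sd baseline heart-rate mean and hourly
#'   noise standard deviation (bpm).
#' @param circadian_amplitude_temp,circadian_amplitude_hr amplitude of the
#'   24-hour sinusoidal diurnal cycle for each channel.
#' @param activity_spike_rate expected number of activity (exercise) spikes
#'   per subject per week; spikes last 1-2 hours, raise both channels, and
#'   are labeled healthy.
#' @param episode_spec an [episode_spec()] describing injected episodes.
#' @param episodes_in_training if `TRUE`, episode onsets may fall anywhere
#'   in the series instead of only in the default test window (robustness
#'   experiments only).
#' @param seed default master seed used by [generate_cohort()].
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [episode_spec()]
#' @export
cohort_config <- function(n_subjects = 2000L,
                          n_weeks = 24L,
                          n_unhealthy_subjects = 613L,
                          n_male = 978L,
                          age_range = c(18L, 50L),
                          healthy_temp_mean = 36.6,
                          healthy_temp_sd = 0.15,
                          healthy_hr_mean = 72,
                          healthy_hr_sd = 3,
                          circadian_amplitude_temp = 0.4,
                          circadian_amplitude_hr = 8,
                          activity_spike_rate = 2,
                          episode_spec = gruae::episode_spec(),
                          episodes_in_training = FALSE,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_weeks = as.integer(n_weeks),
    sampling_interval = 1L,
    n_unhealthy_subjects = as.integer(n_unhealthy_subjects),
    n_male = as.integer(n_male),
    age_range = as.integer(age_range),
    healthy_temp_mean = healthy_temp_mean,
    healthy_temp_sd = healthy_temp_sd,
    healthy_hr_mean = healthy_hr_mean,
    healthy_hr_sd = healthy_hr_sd,
    circadian_amplitude_temp = circadian_amplitude_temp,
    circadian_amplitude_hr = circadian_amplitude_hr,
    activity_spike_rate = activity_spike_rate,
    episode_spec = episode_spec,
    episodes_in_training = isTRUE(episodes_in_training),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_subjects < 1L)
    stop_config("invalid cohort config: n_subjects must be >= 1")
  if (cfg$n_weeks < 1L)
    stop_config("invalid cohort config: n_weeks must be >= 1")
  if (cfg$n_unhealthy_subjects > cfg$n_subjects)
    stop_config("invalid cohort config: n_unhealthy_subjects (",
                cfg$n_unhealthy_subjects, ") exceeds n_subjects (",
                cfg$n_subjects, ")")
  if (cfg$n_male > cfg$n_subjects)
    stop_config("invalid cohort config: n_male (", cfg$n_male,
                ") exceeds n_subjects (", cfg$n_subjects, ")")
  if (cfg$n_unhealthy_subjects < 0L || cfg$n_male < 0L)
    stop_config("invalid cohort config: counts must be nonnegative")
  if (length(cfg$age_range) != 2L || cfg$age_range[1] > cfg$age_range[2])
    stop_config("invalid cohort config: age_range must be an increasing pair")
  if (cfg$healthy_temp_sd <= 0 || cfg$healthy_hr_sd <= 0)
    stop_config("invalid cohort config: noise standard deviations must be > 0")
  if (cfg$activity_spike_rate < 0)
    stop_config("invalid cohort config: activity_spike_rate must be >= 0")
  spec <- cfg$episode_spec
  if (cfg$n_unhealthy_subjects > 0L &&
      spec$fever_temp_range[1] <= cfg$healthy_temp_mean)
    stop_config("invalid cohort config: fever_temp_range lower bound (",
                spec$fever_temp_range[1], ") must exceed healthy_temp_mean (",
                cfg$healthy_temp_mean, ")")
  invisible(cfg)
}

#' Specification of an injected health-issue episode
#'
#' An episode is a contiguous interval of hours during which body
#' temperature is drawn within `fever_temp_range` and heart rate within
#' `episode_hr_range`; the first and last `transition` in-episode hours ramp
#' between the lower bound of each range and the episode's plateau level, so
#' every in-episode value stays inside its configured range. Hours inside
#' the episode are labeled unhealthy; everything outside is untouched.
#'
#' Default value ranges and durations follow the published unhealthy
#' test-set excerpts: elevated temperatures of 37.0-38.0 degrees C, heart
#' rates of 65-169 bpm (unhealthy heart rates may stay in the normal
#' range -- fever with bed rest -- or spike far above it), and short bouts
#' of a few hours (the printed excerpts are 5-6 hour intervals). Such
#' episodes are often only *contextually* anomalous: individual samples
#' can look marginally plausible, and only their timing (sustained
#' night-time elevation, decoupling of the two channels from the shared
#' circadian phase) reveals them.
#'
#' @param onset_window optional integer pair: the hour-index range (within
#'   the series) in which the episode may start. `NULL` means the generator
#'   default (the final test weeks; see [cohort_config()]).
#' @param duration_range integer pair, episode duration in hours.
#' @param fever_temp_range temperature range (degrees C) inside episodes.
#' @param episode_hr_range heart-rate range (bpm) inside episodes.
#' @param transition ramp length in hours at each end of the episode.
#' @return An object of class `episode_spec`.
#' @export
episode_spec <- function(onset_window = NULL,
                         duration_range = c(4L, 12L),
                         fever_temp_range = c(37.0, 38.0),
                         episode_hr_range = c(65, 169),
                         transition = 1L) {
  if (duration_range[1] > duration_range[2] || duration_range[1] < 0)
    stop_config("invalid episode spec: duration_range must be a nonnegative ",
                "increasing pair")
  if (fever_temp_range[1] > fever_temp_range[2])
    stop_config("invalid episode spec: fever_temp_range is empty")
  if (episode_hr_range[1] > episode_hr_range[2])
    stop_config("invalid episode spec: episode_hr_range is empty")
  structure(list(onset_window = if (!is.null(onset_window)) as.integer(onset_window),
                 duration_range = as.integer(duration_range),
                 fever_temp_range = as.numeric(fever_temp_range),
                 episode_hr_range = as.numeric(episode_hr_range),
                 transition = as.integer(transition)),
            class = "episode_spec")
}

#' Construct a single subject's vital-sign series
#'
#' @param subject_id integer identifier.
#' @param sex `"M"` or `"F"`.
#' @param age age in years.
#' @param temperature_c,heart_rate_bpm numeric vectors of equal length.
#' @param label per-hour labels, `"healthy"` or `"unhealthy"`; defaults to
#'   all healthy.
#' @param hour_index 1-based consecutive hour indices.
#' @return An object of class `vital_series`.
#' @export
vital_series <- function(subject_id, sex, age, temperature_c, heart_rate_bpm,
                         label = rep("healthy", length(temperature_c)),
                         hour_index = seq_along(temperature_c)) {
  n <- length(temperature_c)
  if (length(heart_rate_bpm) != n || length(label) != n || length(hour_index) != n)
    stop_format("vital_series: temperature, heart rate, label and hour_index ",
                "must have identical length")
  if (n > 1L && any(diff(hour_index) != 1L))
    stop_format("vital_series: hour_index must increase by exactly 1")
  structure(list(subject_id = as.integer(subject_id),
                 sex = sex, age = as.integer(age),
                 hour_index = as.integer(hour_index),
                 temperature_c = as.numeric(temperature_c),
                 heart_rate_bpm = as.numeric(heart_rate_bpm),
                 label = as.character(label),
                 episodes = data.frame(start_hour = integer(0),
                                       end_hour = integer(0))),
            class = "vital_series")
}

# sample() that never falls into the "sample(5)" scalar trap
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

# Ramped in-range values for one episode: plateau drawn near `base`, first
# and last `transition` hours interpolate from the range floor.
episode_values <- function(n, base, range, jitter_sd, transition) {
  v <- pmin(pmax(base + rnorm(n, 0, jitter_sd), range[1]), range[2])
  r <- min(transition, floor(n / 2))
  if (r > 0L) {
    w <- seq_len(r) / (r + 1)
    v[seq_len(r)] <- range[1] + w * (v[seq_len(r)] - range[1])
    tail_idx <- n - seq_len(r) + 1L
    v[tail_idx] <- range[1] + w * (v[tail_idx] - range[1])
  }
  v
}

#' Inject one health-issue episode into a vital-sign series
#'
#' Draws an episode duration and onset from `spec` (deterministically given
#' `seed`), replaces the in-episode temperature and heart rate with ramped
#' values inside the configured fever ranges, and marks those hours
#' unhealthy. All samples outside the episode are returned bit-identical.
#' A `duration_range` of `c(0, 0)` returns the input unchanged.
#'
#' @param series a [vital_series()].
#' @param spec an [episode_spec()]; a `NULL` `onset_window` means the whole
#'   series.
#' @param seed integer seed for the episode draw.
#' @return The modified `vital_series`, with the episode appended to
#'   `series$episodes`.
#' @export
inject_episode <- function(series, spec = episode_spec(), seed = 1L) {
  stopifnot(inherits(series, "vital_series"))
  H <- length(series$hour_index)
  if (spec$duration_range[2] == 0L) return(series)
  set.seed(seed)
  dur <- resample(seq.int(spec$duration_range[1], spec$duration_range[2]))
  dur <- max(dur, 1L)
  ow <- spec$onset_window %||% c(1L, H)
  lo <- max(ow[1], 1L)
  hi <- min(ow[2], H) - dur + 1L
  if (lo > hi)
    stop_range("inject_episode: no feasible onset; episode of ", dur,
               " hours does not fit in onset window [", ow[1], ", ", ow[2],
               "] of a ", H, "-hour series")
  onset <- resample(seq.int(lo, hi))
  idx <- seq.int(onset, onset + dur - 1L)
  base_t <- runif(1, spec$fever_temp_range[1], spec$fever_temp_range[2])
  base_h <- runif(1, spec$episode_hr_range[1], spec$episode_hr_range[2])
  series$temperature_c[idx] <- episode_values(dur, base_t,
                                              spec$fever_temp_range, 0.1,
                                              spec$transition)
  series$heart_rate_bpm[idx] <- episode_values(dur, base_h,
                                               spec$episode_hr_range, 5,
                                               spec$transition)
  series$label[idx] <- "unhealthy"
  series$episodes <- rbind(series$episodes,
                           data.frame(start_hour = onset,
                                      end_hour = onset + dur - 1L))
  series
}

#' Ground-truth label vector of a series
#'
#' Returns the per-hour truth under the healthy-as-positive convention:
#' 1 for healthy hours, 0 for hours inside an injected episode.
#'
#' @param series a [vital_series()].
#' @return Integer vector aligned with `series$hour_index`.
#' @export
episode_truth <- function(series) {
  stopifnot(inherits(series, "vital_series"))
  as.integer(series$label == "healthy")
}

# Healthy baseline process for one subject: circadian sinusoid + noise +
# Poisson-placed activity spikes. Consumes the current RNG stream.
healthy_signals <- function(cfg, H) {
  hod <- (seq_len(H) - 1L) %% 24L
  circ <- sin(2 * pi * (hod - 8) / 24)
  temp <- cfg$healthy_temp_mean + cfg$circadian_amplitude_temp * circ +
    rnorm(H, 0, cfg$healthy_temp_sd)
  hr <- cfg$healthy_hr_mean + cfg$circadian_amplitude_hr * circ +
    rnorm(H, 0, cfg$healthy_hr_sd)
  n_spk <- rpois(1, cfg$activity_spike_rate * cfg$n_weeks)
  if (n_spk > 0) {
    starts <- sample.int(H, n_spk, replace = TRUE)
    durs <- sample.int(2L, n_spk, replace = TRUE)
    d_hr <- runif(n_spk, 25, 55)
    d_t <- runif(n_spk, 0.2, 0.6)
    for (k in seq_len(n_spk)) {
      idx <- seq.int(starts[k], min(starts[k] + durs[k] - 1L, H))
      hr[idx] <- hr[idx] + d_hr[k]
      temp[idx] <- temp[idx] + d_t[k]
    }
  }
  list(temperature_c = temp, heart_rate_bpm = hr)
}

# Default episode onset window: the final sixth of the study (for the
# 24-week default, weeks 21-24), so training weeks stay healthy-only.
default_onset_window <- function(cfg, H) {
  if (cfg$episodes_in_training) return(c(1L, H))
  start_week <- floor(cfg$n_weeks * 5 / 6)
  c(start_week * HOURS_PER_WEEK + 1L, H)
}

#' Generate a synthetic labeled cohort
#'
#' Simulates `config$n_subjects` independent hourly bivariate vital-sign
#' series of `config$n_weeks * 168` hours each. Exactly
#' `config$n_unhealthy_subjects` subjects (chosen at random) carry one
#' injected episode; activity spikes occur in all subjects and are labeled
#' healthy. Generation is bit-reproducible given `(config, seed)`: each
#' subject has its own pseudorandom stream derived from the master seed and
#' the subject id.
#'
#' @param config a [cohort_config()].
#' @param seed master seed; defaults to `config$seed`.
#' @return An object of class `vital_cohort`: a list with elements
#'   `config`, `seed`, `subjects` (subject_id, sex, age, unhealthy),
#'   `data` (subject_id, hour_index, temperature_c, heart_rate_bpm, label),
#'   `episodes` (subject_id, start_hour, end_hour), `split`, and `n_hours`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 3, n_weeks = 1,
#'                                      n_unhealthy_subjects = 0,
#'                                      n_male = 2), seed = 7)
#' nrow(coh$data)  # 3 * 168
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  H <- config$n_weeks * HOURS_PER_WEEK
  n <- config$n_subjects

  set.seed(derive_seed(seed, 0L))
  sex <- resample(c(rep("M", config$n_male), rep("F", n - config$n_male)), n)
  age <- sample(seq.int(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  unhealthy_ids <- sort(resample(seq_len(n), config$n_unhealthy_subjects))
  is_unhealthy <- logical(n)
  is_unhealthy[unhealthy_ids] <- TRUE

  spec <- config$episode_spec
  if (is.null(spec$onset_window)) {
    spec$onset_window <- default_onset_window(config, H)
  }

  temp_l <- vector("list", n)
  hr_l <- vector("list", n)
  lab_l <- vector("list", n)
  epi_l <- vector("list", n)
  for (sid in seq_len(n)) {
    set.seed(derive_seed(seed, sid))
    sig <- healthy_signals(config, H)
    ser <- vital_series(sid, sex[sid], age[sid],
                        sig$temperature_c, sig$heart_rate_bpm)
    if (is_unhealthy[sid]) {
      ser <- inject_episode(ser, spec, seed = derive_seed(seed, n + sid))
      epi_l[[sid]] <- cbind(subject_id = sid, ser$episodes)
    }
    temp_l[[sid]] <- ser$temperature_c
    hr_l[[sid]] <- ser$heart_rate_bpm
    lab_l[[sid]] <- ser$label
  }

  episodes <- do.call(rbind, c(list(data.frame(subject_id = integer(0),
                                               start_hour = integer(0),
                                               end_hour = integer(0))),
                               epi_l[!vapply(epi_l, is.null, TRUE)]))
  cohort <- list(
    config = config,
    seed = as.integer(seed),
    subjects = data.frame(subject_id = seq_len(n), sex = sex, age = age,
                          unhealthy = is_unhealthy),
    data = data.frame(subject_id = rep(seq_len(n), each = H),
                      hour_index = rep(seq_len(H), times = n),
                      temperature_c = unlist(temp_l),
                      heart_rate_bpm = unlist(hr_l),
                      label = unlist(lab_l)),
    episodes = episodes,
    split = "full",
    n_hours = H
  )
  class(cohort) <- "vital_cohort"
  cohort
}

#' Extract one subject's series from a cohort
#'
#' @param cohort a `vital_cohort`.
#' @param subject_id subject identifier.
#' @return A [vital_series()].
#' @export
cohort_series <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "vital_cohort"))
  rows <- cohort$data$subject_id == subject_id
  if (!any(rows)) stop_range("cohort_series: no subject ", subject_id)
  subj <- cohort$subjects[cohort$subjects$subject_id == subject_id, ]
  ser <- vital_series(subject_id, subj$sex, subj$age,
                      cohort$data$temperature_c[rows],
                      cohort$data$heart_rate_bpm[rows],
                      cohort$data$label[rows],
                      cohort$data$hour_index[rows])
  epi <- cohort$episodes[cohort$episodes$subject_id == subject_id,
                         c("start_hour", "end_hour")]
  rownames(epi) <- NULL
  ser$episodes <- epi
  ser
}

#' @export
print.vital_cohort <- function(x, ...) {
  cat(sprintf("<vital_cohort: %d subjects x %d hours (%s split), %d samples, %d with episodes>\n",
              nrow(x$subjects), x$n_hours, x$split, nrow(x$data),
              sum(x$subjects$unhealthy)))
  invisible(x)
}

#' @export
print.vital_series <- function(x, ...) {
  cat(sprintf("<vital_series: subject %d (%s, %d y), %d hours, %d unhealthy>\n",
              x$subject_id, x$sex, x$age, length(x$hour_index),
              sum(x$label == "unhealthy")))
  invisible(x)
}
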