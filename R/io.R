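VITALS_COLUMNS <- c("subject_id", "sex", "age", "split", "hour_index",
                    "temperature_c", "heart_rate_bpm", "label")

#' Write a cohort to a delimited text file
#'
#' One row per subject-hour with columns `subject_id, sex, age, split,
#' hour_index, temperature_c, heart_rate_bpm, label` (comma-separated,
#' UTF-8, '.' decimal, header mandatory).
#'
#' @param cohort a `vital_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_vitals <- function(cohort, path) {
  stopifnot(inherits(cohort, "vital_cohort"))
  d <- cohort$data
  subj <- cohort$subjects
  i <- match(d$subject_id, subj$subject_id)
  out <- data.table::data.table(
    subject_id = d$subject_id, sex = subj$sex[i], age = subj$age[i],
    split = cohort$split, hour_index = d$hour_index,
    temperature_c = d$temperature_c, heart_rate_bpm = d$heart_rate_bpm,
    label = d$label)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a cohort from a delimited text file
#'
#' Validates the canonical header, numeric cells and per-subject
#' consecutive hour indices; episode intervals are reconstructed from the
#' unhealthy-label runs. Format violations raise an error naming the
#' offending column or row.
#'
#' @param path CSV path written by [write_vitals()].
#' @return A `vital_cohort` (its `config` is `NULL`: the generative
#'   parameters are not stored in the sample table).
#' @export
read_vitals <- function(path) {
  d <- data.table::fread(path)
  missing <- setdiff(VITALS_COLUMNS, names(d))
  if (length(missing) > 0)
    stop_format("read_vitals: missing column(s): ",
                paste(missing, collapse = ", "))
  for (col in c("subject_id", "age", "hour_index", "temperature_c",
                "heart_rate_bpm")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_format("read_vitals: non-numeric value in column '", col,
                  "' at row ", bad)
    }
  }
  d <- as.data.frame(d)
  ord <- order(d$subject_id, d$hour_index)
  if (is.unsorted(ord)) d <- d[ord, ]
  per_subject <- split(seq_len(nrow(d)), d$subject_id)
  for (rows in per_subject) {
    hi <- d$hour_index[rows]
    if (length(hi) > 1L && any(diff(hi) != 1L)) {
      bad <- rows[which(diff(hi) != 1L)[1] + 1L]
      stop_format("read_vitals: non-consecutive hour_index at row ", bad,
                  " (subject ", d$subject_id[bad], ")")
    }
  }

  ids <- unique(d$subject_id)
  first <- match(ids, d$subject_id)
  subjects <- data.frame(subject_id = as.integer(ids), sex = d$sex[first],
                         age = as.integer(d$age[first]),
                         unhealthy = as.logical(
                           tapply(d$label == "unhealthy", d$subject_id, any)[as.character(ids)]))
  episodes <- episodes_from_labels(d)
  H <- length(per_subject[[1]])
  cohort <- list(config = NULL, seed = NA_integer_,
                 subjects = subjects,
                 data = data.frame(subject_id = as.integer(d$subject_id),
                                   hour_index = as.integer(d$hour_index),
                                   temperature_c = d$temperature_c,
                                   heart_rate_bpm = d$heart_rate_bpm,
                                   label = d$label),
                 episodes = episodes,
                 split = d$split[1],
                 n_hours = H)
  class(cohort) <- "vital_cohort"
  cohort
}

# Contiguous unhealthy runs per subject -> episode table.
episodes_from_labels <- function(d) {
  out <- list()
  for (sid in unique(d$subject_id)) {
    rows <- d$subject_id == sid
    lab <- d$label[rows] == "unhealthy"
    if (!any(lab)) next
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hi <- d$hour_index[rows]
    keep <- r$values
    out[[length(out) + 1L]] <- data.frame(subject_id = as.integer(sid),
                                          start_hour = hi[starts[keep]],
                                          end_hour = hi[ends[keep]])
  }
  if (length(out) == 0)
    return(data.frame(subject_id = integer(0), start_hour = integer(0),
                      end_hour = integer(0)))
  do.call(rbind, out)
}

#' Write an episode-truth table
#'
#' @param cohort a `vital_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(cohort, path) {
  data.table::fwrite(cohort$episodes, path)
  invisible(path)
}

#' Write an alarm log
#'
#' @param alarms alarm data frame from [monitor_stream()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_alarms <- function(alarms, path) {
  data.table::fwrite(alarms, path)
  invisible(path)
}

CHECKPOINT_VERSION <- 1L

#' Save a trained model (with its normalizer) to a checkpoint file
#'
#' A versioned JSON container holding the model kind, hyperparameters, all
#' weight matrices at full precision (17 significant digits, so save/load
#' reproduces forward outputs bit-identically), the fitted normalizer, the
#' training configuration and loss history, and optionally the calibrated
#' alarm threshold.
#'
#' @param model a `gru_ae_model` or `ae_model`.
#' @param normalizer the training-time [fit_normalizer()] result.
#' @param path output path (.json).
#' @param threshold optional calibrated alarm threshold to store.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(model, normalizer, path, threshold = NULL) {
  kind <- if (inherits(model, "gru_ae_model")) "gru_ae" else "ae"
  ck <- list(
    format_version = CHECKPOINT_VERSION,
    model_kind = kind,
    hyperparameters = list(input_size = model$params$input_size,
                           hidden_sizes = model$params$hidden_sizes),
    weights = if (kind == "gru_ae") {
      list(layers = lapply(model$params$layers, function(l)
        l[c("Wu", "Uu", "Wr", "Ur", "Wc", "Uc")]),
        Wy = model$params$Wy, by = model$params$by)
    } else {
      model$params$weights
    },
    normalizer = c(unclass(normalizer),
                   list(channels = names(normalizer$min))),
    train_config = unclass(model$config),
    seed = model$config$seed,
    loss_history = model$loss_history,
    threshold = threshold
  )
  jsonlite::write_json(ck, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path written by [write_checkpoint()].
#' @return List with `model` (class restored), `normalizer`, and
#'   `threshold` (or `NULL`).
#' @export
read_checkpoint <- function(path) {
  ck <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (is.null(ck$format_version) || ck$format_version != CHECKPOINT_VERSION)
    stop_format("read_checkpoint: unsupported format version")
  hs <- as.integer(ck$hyperparameters$hidden_sizes)
  input_size <- as.integer(ck$hyperparameters$input_size)
  cfg <- ck$train_config
  config <- train_config(cfg$learning_rate, cfg$epochs, cfg$optimizer,
                         cfg$batch_size, cfg$seed)
  if (ck$model_kind == "gru_ae") {
    params <- gru_ae_params(input_size, hs, seed = 1L)
    for (k in 1:3) {
      for (nm in c("Wu", "Uu", "Wr", "Ur", "Wc", "Uc")) {
        params$layers[[k]][[nm]] <- matrix(ck$weights$layers[[k]][[nm]],
                                           nrow = nrow(params$layers[[k]][[nm]]))
      }
    }
    params$Wy <- matrix(ck$weights$Wy, nrow = input_size)
    params$by <- as.numeric(ck$weights$by)
    model <- structure(list(params = params,
                            loss_history = as.numeric(ck$loss_history),
                            config = config),
                       class = "gru_ae_model")
  } else {
    params <- ae_params(input_size, hs, seed = 1L)
    for (k in 1:4) {
      wn <- paste0("W", k); bn <- paste0("b", k)
      params$weights[[wn]] <- matrix(ck$weights[[wn]],
                                     nrow = nrow(params$weights[[wn]]))
      params$weights[[bn]] <- as.numeric(ck$weights[[bn]])
    }
    model <- structure(list(params = params,
                            loss_history = as.numeric(ck$loss_history),
                            config = config),
                       class = "ae_model")
  }
  chan <- unlist(ck$normalizer$channels)
  norm <- structure(list(min = structure(as.numeric(ck$normalizer$min),
                                         names = chan),
                         max = structure(as.numeric(ck$normalizer$max),
                                         names = chan),
                         target_low = ck$normalizer$target_low,
                         target_high = ck$normalizer$target_high),
                    class = "vital_normalizer")
  list(model = model, normalizer = norm,
       threshold = if (!is.null(ck$threshold)) as.numeric(ck$threshold))
}

#' The printed unhealthy test-set excerpts
#'
#' Returns the two published excerpts of unhealthy biomedical signals:
#' test set 1 (a 20-year-old male; time sequence 667-672) and test set 2
#' (a 50-year-old female; 131-135 and 601-606), 17 rows in total. The
#' heart-rate value 1140 bpm at time 604 of test set 2 is physiologically
#' impossible and carried verbatim with `suspect = TRUE`; setting
#' `correct_suspect = TRUE` replaces it with the plausible 114 bpm.
#'
#' @param correct_suspect replace the suspect 1140 bpm reading by 114.
#' @return A data frame with columns `test_set, time_sequence,
#'   temperature_c, heart_rate_bpm, suspect`.
#' @export
load_table1_fixture <- function(correct_suspect = FALSE) {
  path <- system.file("extdata", "table1_unhealthy_signals.csv",
                      package = "gruae", mustWork = TRUE)
  d <- utils::read.csv(path)
  if (correct_suspect) {
    d$heart_rate_bpm[d$suspect] <- 114
  }
  d
}
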