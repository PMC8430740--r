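#' Training configuration
#'
#' Defaults follow the reference protocol: learning rate 0.01 and 4000
#' training epochs. The optimizer is an adaptive first-order method (Adam)
#' by default; `optimizer = "sgd"` selects literal fixed-rate gradient
#' descent. The batch size (number of windows per gradient step for the
#' GRU-AE, samples for the feedforward AE) is not part of the reference
#' protocol; 64 is the package default.
#'
#' @param learning_rate positive step size.
#' @param epochs number of passes over the training windows.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 4000L,
                         optimizer = c("adam", "sgd"), batch_size = 64L,
                         seed = 1L) {
  if (learning_rate <= 0) stop_config("train_config: learning_rate must be > 0")
  if (epochs < 1L) stop_config("train_config: epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = match.arg(optimizer),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize GRU-AE parameters
#'
#' The encoder/decoder stack is three GRU layers of 128, 32 and 128 hidden
#' units (the bottleneck in the middle), followed by a fully connected
#' sigmoid head `y_t = sigmoid(Wy h3_t + by)` mapping back to the channel
#' count. Gate weights carry no bias terms; only the head has a bias.
#'
#' @param input_size number of signal channels (default 2: temperature,
#'   heart rate).
#' @param hidden_sizes the three layer widths.
#' @param seed initialization seed.
#' @return An object of class `gru_ae_params`.
#' @export
gru_ae_params <- function(input_size = 2L, hidden_sizes = c(128L, 32L, 128L),
                          seed = 1L) {
  set.seed(seed)
  ins <- c(input_size, hidden_sizes[1], hidden_sizes[2])
  layers <- lapply(1:3, function(k)
    gru_layer_params(ins[k], hidden_sizes[k], seed = NULL))
  s <- sqrt(1 / hidden_sizes[3])
  structure(list(layers = layers,
                 Wy = matrix(runif(input_size * hidden_sizes[3], -s, s),
                             input_size, hidden_sizes[3]),
                 by = numeric(input_size),
                 input_size = as.integer(input_size),
                 hidden_sizes = as.integer(hidden_sizes)),
            class = "gru_ae_params")
}

zero_states <- function(params, n = 1L) {
  lapply(params$hidden_sizes, function(h) matrix(0, n, h))
}

#' GRU-AE forward pass over one sequence (reference implementation)
#'
#' Pure-R double-precision forward pass used for monitoring single streams
#' and as the verification oracle for the batched C++ path. Hidden states
#' chain through `h1 -> h2 -> h3` layer by layer; the head reconstructs
#' every timestep.
#'
#' @param x numeric matrix `T x input_size` of normalized samples.
#' @param params a [gru_ae_params()].
#' @param states list of three hidden-state vectors carried from the
#'   previous call (streaming), or `NULL` for zero initialization.
#' @return List with `y` (`T x input_size` reconstruction) and `states`
#'   (final states of the three layers, for streaming continuation).
#' @export
gru_ae_forward <- function(x, params, states = NULL) {
  stopifnot(inherits(params, "gru_ae_params"))
  x <- rbind(x)
  if (ncol(x) != params$input_size)
    stop_format("gru_ae_forward: expected ", params$input_size,
                " channels, got ", ncol(x))
  if (any(x < -1 | x > 2))
    warning("gru_ae_forward: input outside the plausible normalized band ",
            "(-1, 2); anomalies may exceed the training range", call. = FALSE)
  if (is.null(states)) states <- lapply(params$hidden_sizes, numeric)
  f1 <- gru_layer_forward(x, params$layers[[1]], states[[1]])
  f2 <- gru_layer_forward(f1$h, params$layers[[2]], states[[2]])
  f3 <- gru_layer_forward(f2$h, params$layers[[3]], states[[3]])
  y <- sigmoid(f3$h %*% t(params$Wy) +
                 matrix(params$by, nrow(x), params$input_size, byrow = TRUE))
  list(y = y, states = list(f1$h_final, f2$h_final, f3$h_final))
}

#' Per-timestep reconstruction loss
#'
#' The anomaly score of the method: `Loss_t = 0.5 * sum_channels
#' (y_t - x_t)^2`, and the sequence total is the sum over timesteps.
#'
#' @param x original (normalized) segment, `T x channels`.
#' @param y reconstruction of the same shape.
#' @return An object of class `loss_trace`: list with `loss_t` (length-T
#'   vector) and `total`.
#' @export
reconstruction_loss <- function(x, y) {
  x <- rbind(x); y <- rbind(y)
  if (!all(dim(x) == dim(y)))
    stop_format("reconstruction_loss: shape mismatch (",
                paste(dim(x), collapse = "x"), " vs ",
                paste(dim(y), collapse = "x"), ")")
  lt <- 0.5 * rowSums((y - x)^2)
  structure(list(loss_t = lt, total = sum(lt)), class = "loss_trace")
}

# Reference full-model gradient (double precision, single window): used by
# the test suite to validate the batched C++ path against finite
# differences. Returns loss and gradients for every parameter.
gru_ae_grad_ref <- function(params, x, states = NULL) {
  x <- rbind(x)
  if (is.null(states)) states <- lapply(params$hidden_sizes, numeric)
  f1 <- gru_layer_forward_cache(x, params$layers[[1]], states[[1]])
  f2 <- gru_layer_forward_cache(f1$h, params$layers[[2]], states[[2]])
  f3 <- gru_layer_forward_cache(f2$h, params$layers[[3]], states[[3]])
  Tn <- nrow(x)
  y <- sigmoid(f3$h %*% t(params$Wy) +
                 matrix(params$by, Tn, params$input_size, byrow = TRUE))
  e <- y - x
  loss <- 0.5 * sum(e^2)
  da_y <- e * y * (1 - y)
  gWy <- t(da_y) %*% f3$h
  gby <- colSums(da_y)
  dH3 <- da_y %*% params$Wy
  b3 <- gru_layer_backward(f3$cache, params$layers[[3]], dH3)
  b2 <- gru_layer_backward(f2$cache, params$layers[[2]], b3$dX)
  b1 <- gru_layer_backward(f1$cache, params$layers[[1]], b2$dX)
  list(loss = loss,
       grads = list(layers = list(b1$grads, b2$grads, b3$grads),
                    Wy = gWy, by = gby))
}

# ---- parameter flattening and Adam (shared by both model kinds) ----

flatten_params <- function(p) {
  if (inherits(p, "gru_ae_params")) {
    c(unlist(lapply(p$layers, function(l) l[c("Wu", "Uu", "Wr", "Ur", "Wc", "Uc")]),
             recursive = FALSE),
      list(Wy = p$Wy, by = p$by))
  } else {
    p$weights
  }
}

grads_flat <- function(g, kind) {
  if (kind == "gru_ae") {
    c(unlist(lapply(g$layers, function(l) l[c("Wu", "Uu", "Wr", "Ur", "Wc", "Uc")]),
             recursive = FALSE),
      list(Wy = g$Wy, by = as.numeric(g$by)))
  } else {
    g
  }
}

unflatten_params <- function(flat, proto) {
  if (inherits(proto, "gru_ae_params")) {
    for (k in 1:3) {
      for (nm in c("Wu", "Uu", "Wr", "Ur", "Wc", "Uc")) {
        proto$layers[[k]][[nm]] <- flat[[(k - 1) * 6 + match(nm, c("Wu", "Uu", "Wr", "Ur", "Wc", "Uc"))]]
      }
    }
    proto$Wy <- flat$Wy
    proto$by <- as.numeric(flat$by)
  } else {
    proto$weights <- flat
  }
  proto
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (i in seq_along(flat)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    flat[[i]] <- flat[[i]] -
      lr * (state$m[[i]] / b1t) / (sqrt(state$v[[i]] / b2t) + eps)
  }
  list(flat = flat, state = state)
}

sgd_step <- function(flat, grads, lr) {
  for (i in seq_along(flat)) flat[[i]] <- flat[[i]] - lr * grads[[i]]
  flat
}

windows_to_cube <- function(windows) {
  if (inherits(windows, "window_batch")) windows <- windows$windows
  stopifnot(length(dim(windows)) == 3L)
  aperm(windows, c(1, 3, 2))  # N x L x C -> N x C x T for the C++ core
}

#' Train the GRU autoencoder on healthy windows
#'
#' Minimizes the total reconstruction loss `sum_t 0.5 ||y_t - x_t||^2` over
#' the training windows by minibatch gradient descent (Adam by default).
#' Training data are expected to be healthy-only and normalized; the model
#' needs no labels. Deterministic given `config$seed`.
#'
#' @param windows a [make_windows()]/[cohort_windows()] batch (normalized),
#'   or a plain `n x L x channels` array.
#' @param config a [train_config()].
#' @param params optional initial [gru_ae_params()]; by default initialized
#'   from `config$seed` with the reference widths 128/32/128.
#' @param hidden_sizes layer widths used when `params` is not given.
#' @param verbose print the epoch loss every `verbose` epochs (0 = silent).
#' @return An object of class `gru_ae_model`: list with `params`,
#'   `loss_history` (mean per-timestep loss per epoch), and `config`.
#' @export
train_gru_ae <- function(windows, config = train_config(), params = NULL,
                         hidden_sizes = c(128L, 32L, 128L), verbose = 0L) {
  X <- windows_to_cube(windows)
  n <- dim(X)[1]; Tn <- dim(X)[3]
  if (is.null(params))
    params <- gru_ae_params(dim(X)[2], hidden_sizes, seed = config$seed)
  set.seed(derive_seed(config$seed, 1L))
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      params <- unflatten_params(flat, params)
      res <- cpp_gru_ae_run(X[b, , , drop = FALSE], params, NULL,
                            TRUE, FALSE)
      ep_loss <- ep_loss + res$loss
      g <- grads_flat(res$grads, "gru_ae")
      g <- lapply(g, function(x) x / length(b))  # mean-over-windows scale
      if (config$optimizer == "adam") {
        st <- adam_step(flat, g, opt, config$learning_rate)
        flat <- st$flat; opt <- st$state
      } else {
        flat <- sgd_step(flat, g, config$learning_rate)
      }
    }
    history[ep] <- ep_loss / (n * Tn)
    if (!is.finite(history[ep]))
      stop("train_gru_ae: loss diverged at epoch ", ep,
           "; try a smaller learning rate")
    if (verbose > 0L && ep %% verbose == 0L)
      message(sprintf("epoch %d: mean per-timestep loss %.6f", ep, history[ep]))
  }
  structure(list(params = unflatten_params(flat, params),
                 loss_history = history, config = config),
            class = "gru_ae_model")
}

#' Initialize feedforward autoencoder parameters
#'
#' The memoryless baseline: a per-sample map through sigmoid layers
#' `input -> 128 -> 32 -> 128 -> input` (encoder `h = f(Ax + b)`, decoder
#' `y = g(Ch + d)` chained through the stack). It sees each hourly sample
#' in isolation, so it cannot exploit circadian context.
#'
#' @inheritParams gru_ae_params
#' @return An object of class `ae_params` with a `weights` list
#'   `W1, b1, ..., W4, b4`.
#' @export
ae_params <- function(input_size = 2L, hidden_sizes = c(128L, 32L, 128L),
                      seed = 1L) {
  set.seed(seed)
  dims <- c(input_size, hidden_sizes, input_size)
  w <- list()
  for (k in 1:4) {
    s <- sqrt(1 / dims[k + 1])
    w[[paste0("W", k)]] <- matrix(runif(dims[k + 1] * dims[k], -s, s),
                                  dims[k + 1], dims[k])
    w[[paste0("b", k)]] <- numeric(dims[k + 1])
  }
  structure(list(weights = w, input_size = as.integer(input_size),
                 hidden_sizes = as.integer(hidden_sizes)),
            class = "ae_params")
}

#' Feedforward autoencoder forward pass
#'
#' Reconstructs each row of `x` independently of all others (permuting
#' input rows permutes outputs identically).
#'
#' @param x numeric matrix `n x input_size` of normalized samples.
#' @param params an [ae_params()].
#' @return Reconstruction matrix of the same shape.
#' @export
ae_forward <- function(x, params) {
  stopifnot(inherits(params, "ae_params"))
  x <- rbind(x)
  if (ncol(x) != params$input_size)
    stop_format("ae_forward: expected ", params$input_size,
                " channels, got ", ncol(x))
  z <- x
  w <- params$weights
  for (k in 1:4) {
    z <- sigmoid(z %*% t(w[[paste0("W", k)]]) +
                   matrix(w[[paste0("b", k)]], nrow(z),
                          length(w[[paste0("b", k)]]), byrow = TRUE))
  }
  z
}

#' Train the feedforward autoencoder baseline
#'
#' Same protocol as [train_gru_ae()] but on individual hourly samples with
#' per-sample loss `0.5 ||x - x'||^2`.
#'
#' @param samples numeric matrix `n x input_size` of normalized healthy
#'   training samples (windows are accepted and unrolled).
#' @inheritParams train_gru_ae
#' @return An object of class `ae_model`.
#' @export
train_ae <- function(samples, config = train_config(), params = NULL,
                     hidden_sizes = c(128L, 32L, 128L), verbose = 0L) {
  if (inherits(samples, "window_batch") || length(dim(samples)) == 3L) {
    if (inherits(samples, "window_batch")) samples <- samples$windows
    samples <- matrix(samples, ncol = dim(samples)[3])  # (n*L) x channels
  }
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (is.null(params))
    params <- ae_params(ncol(samples), hidden_sizes, seed = config$seed)
  set.seed(derive_seed(config$seed, 2L))
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      params$weights <- flat
      res <- cpp_ae_run(samples[b, , drop = FALSE], flat, TRUE, FALSE)
      ep_loss <- ep_loss + res$loss
      g <- lapply(res$grads, function(x) x / length(b))
      g$b1 <- as.numeric(g$b1); g$b2 <- as.numeric(g$b2)
      g$b3 <- as.numeric(g$b3); g$b4 <- as.numeric(g$b4)
      if (config$optimizer == "adam") {
        st <- adam_step(flat, g, opt, config$learning_rate)
        flat <- st$flat; opt <- st$state
      } else {
        flat <- sgd_step(flat, g, config$learning_rate)
      }
    }
    history[ep] <- ep_loss / n
    if (!is.finite(history[ep]))
      stop("train_ae: loss diverged at epoch ", ep,
           "; try a smaller learning rate")
    if (verbose > 0L && ep %% verbose == 0L)
      message(sprintf("epoch %d: mean per-sample loss %.6f", ep, history[ep]))
  }
  params$weights <- flat
  structure(list(params = params, loss_history = history, config = config),
            class = "ae_model")
}

#' Per-hour loss traces of a model over a normalized sequence
#'
#' Generic anomaly-scoring entry point shared by the monitor and the
#' evaluation suite.
#'
#' @param model a `gru_ae_model` or `ae_model`.
#' @param x normalized matrix `T x channels`.
#' @param states carried GRU states (ignored by the feedforward model).
#' @return List with `loss_t` and final `states` (NULL for the AE).
#' @export
model_loss_trace <- function(model, x, states = NULL) {
  if (inherits(model, "gru_ae_model")) {
    fwd <- gru_ae_forward(x, model$params, states)
    lt <- reconstruction_loss(x, fwd$y)
    list(loss_t = lt$loss_t, states = fwd$states)
  } else if (inherits(model, "ae_model")) {
    y <- ae_forward(x, model$params)
    lt <- reconstruction_loss(x, y)
    list(loss_t = lt$loss_t, states = NULL)
  } else {
    stop_format("model_loss_trace: unknown model class")
  }
}

# Batched per-subject loss traces over a cohort (all subjects share the
# same series length). Returns a subjects x T matrix of Loss_t values on
# the normalized scale, using the fast C++ path. init_states, if given,
# is a list of three n_subjects x hidden matrices.
cohort_loss_matrix <- function(model, cohort, normalizer, init_states = NULL) {
  ids <- cohort$subjects$subject_id
  Tn <- cohort$n_hours
  n <- length(ids)
  norm <- apply_normalizer(normalizer,
                           cbind(cohort$data$temperature_c,
                                 cohort$data$heart_rate_bpm))
  # data is ordered by subject then hour
  X <- array(NA_real_, dim = c(n, 2, Tn))
  for (i in seq_len(n)) {
    rows <- seq.int((i - 1L) * Tn + 1L, i * Tn)
    X[i, , ] <- t(norm[rows, , drop = FALSE])
  }
  if (inherits(model, "gru_ae_model")) {
    res <- cpp_gru_ae_run(X, model$params, init_states, FALSE, FALSE)
    out <- res$loss_t
    attr(out, "states") <- res$states
  } else {
    # rows of S: subject index varies fastest, so loss_i refolds to n x T
    S <- matrix(aperm(X, c(1, 3, 2)), ncol = 2)
    res <- cpp_ae_run(S, model$params$weights, FALSE, FALSE)
    out <- matrix(res$loss_i, n, Tn)
  }
  rownames(out) <- ids
  out
}
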