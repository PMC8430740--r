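#' Parameters of one GRU layer
#'
#' A gated recurrent unit layer with update gate `u`, reset gate `r` and
#' candidate state, parameterized by six weight matrices and no bias terms:
#' input-to-hidden `Wu`, `Wr`, `Wc` (hidden x input) and hidden-to-hidden
#' `Uu`, `Ur`, `Uc` (hidden x hidden). Weights are initialized uniformly in
#' `[-sqrt(1/hidden_size), sqrt(1/hidden_size)]`.
#'
#' @param input_size input dimension.
#' @param hidden_size number of hidden units.
#' @param seed integer seed for the initialization draw; `NULL` leaves the
#'   RNG stream untouched.
#' @return An object of class `gru_layer_params`.
#' @export
gru_layer_params <- function(input_size, hidden_size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sqrt(1 / hidden_size)
  rnd <- function(r, c) matrix(runif(r * c, -s, s), r, c)
  structure(list(Wu = rnd(hidden_size, input_size),
                 Uu = rnd(hidden_size, hidden_size),
                 Wr = rnd(hidden_size, input_size),
                 Ur = rnd(hidden_size, hidden_size),
                 Wc = rnd(hidden_size, input_size),
                 Uc = rnd(hidden_size, hidden_size),
                 input_size = as.integer(input_size),
                 hidden_size = as.integer(hidden_size)),
            class = "gru_layer_params")
}

check_gru_shapes <- function(params, x, h_prev) {
  if (length(x) != params$input_size)
    stop_format("gru_cell_step: input has length ", length(x),
                ", expected ", params$input_size)
  if (length(h_prev) != params$hidden_size)
    stop_format("gru_cell_step: hidden state has length ", length(h_prev),
                ", expected ", params$hidden_size)
}

#' One GRU cell update
#'
#' Computes, with elementwise products:
#' \deqn{u_t = \sigma(W_u x_t + U_u h_{t-1})}
#' \deqn{r_t = \sigma(W_r x_t + U_r h_{t-1})}
#' \deqn{\tilde h_t = \tanh(W x_t + r_t \odot (U h_{t-1}))}
#' \deqn{h_t = u_t \odot h_{t-1} + (1 - u_t) \odot \tilde h_t}
#'
#' The update gate decides how much of the previous state is retained; with
#' zero-initialized states every component of `h_t` stays in (-1, 1).
#'
#' @param x input vector at time t (length `input_size`).
#' @param h_prev previous hidden state (length `hidden_size`).
#' @param params a [gru_layer_params()].
#' @return The new hidden state `h_t` (numeric vector).
#' @export
gru_cell_step <- function(x, h_prev, params) {
  check_gru_shapes(params, x, h_prev)
  u <- sigmoid(drop(params$Wu %*% x + params$Uu %*% h_prev))
  r <- sigmoid(drop(params$Wr %*% x + params$Ur %*% h_prev))
  hc <- tanh(drop(params$Wc %*% x) + r * drop(params$Uc %*% h_prev))
  u * h_prev + (1 - u) * hc
}

#' Run a GRU layer over a sequence
#'
#' Chains [gru_cell_step()] over the rows of `sequence`, starting from
#' `h0` (zero by default), and returns every hidden state plus the final
#' state for streaming continuation.
#'
#' @param sequence numeric matrix, `T x input_size` (one row per timestep).
#' @param params a [gru_layer_params()].
#' @param h0 initial hidden state; defaults to the zero vector.
#' @return List with `h` (`T x hidden_size` matrix of hidden states) and
#'   `h_final` (last state).
#' @export
gru_layer_forward <- function(sequence, params, h0 = NULL) {
  sequence <- rbind(sequence)
  h <- h0 %||% numeric(params$hidden_size)
  stopifnot(all(is.finite(h)))
  T_len <- nrow(sequence)
  H <- matrix(NA_real_, T_len, params$hidden_size)
  for (t in seq_len(T_len)) {
    h <- gru_cell_step(sequence[t, ], h, params)
    H[t, ] <- h
  }
  list(h = H, h_final = h)
}

# Forward pass caching every intermediate needed by backpropagation
# through time. Internal.
gru_layer_forward_cache <- function(sequence, params, h0 = NULL) {
  sequence <- rbind(sequence)
  h <- h0 %||% numeric(params$hidden_size)
  T_len <- nrow(sequence)
  nh <- params$hidden_size
  cache <- list(u = matrix(0, T_len, nh), r = matrix(0, T_len, nh),
                hc = matrix(0, T_len, nh), huc = matrix(0, T_len, nh),
                h_prev = matrix(0, T_len, nh), x = sequence)
  H <- matrix(NA_real_, T_len, nh)
  for (t in seq_len(T_len)) {
    x <- sequence[t, ]
    u <- sigmoid(drop(params$Wu %*% x + params$Uu %*% h))
    r <- sigmoid(drop(params$Wr %*% x + params$Ur %*% h))
    huc <- drop(params$Uc %*% h)
    hc <- tanh(drop(params$Wc %*% x) + r * huc)
    cache$u[t, ] <- u; cache$r[t, ] <- r; cache$hc[t, ] <- hc
    cache$huc[t, ] <- huc; cache$h_prev[t, ] <- h
    h <- u * h + (1 - u) * hc
    H[t, ] <- h
  }
  list(h = H, h_final = h, cache = cache)
}

# Backpropagation through time for one layer. dH is the T x hidden matrix
# of loss gradients with respect to each emitted hidden state. Returns
# gradients for the six weight matrices, the input sequence, and h0.
gru_layer_backward <- function(cache, params, dH) {
  T_len <- nrow(dH)
  g <- list(Wu = 0 * params$Wu, Uu = 0 * params$Uu,
            Wr = 0 * params$Wr, Ur = 0 * params$Ur,
            Wc = 0 * params$Wc, Uc = 0 * params$Uc)
  dX <- matrix(0, T_len, params$input_size)
  dh_carry <- numeric(params$hidden_size)
  for (t in rev(seq_len(T_len))) {
    dh <- dH[t, ] + dh_carry
    u <- cache$u[t, ]; r <- cache$r[t, ]; hc <- cache$hc[t, ]
    h_prev <- cache$h_prev[t, ]; x <- cache$x[t, ]
    da_u <- dh * (h_prev - hc) * u * (1 - u)
    da_c <- dh * (1 - u) * (1 - hc^2)
    da_r <- da_c * cache$huc[t, ] * r * (1 - r)
    dacr <- da_c * r
    g$Wu <- g$Wu + tcrossprod(da_u, x)
    g$Uu <- g$Uu + tcrossprod(da_u, h_prev)
    g$Wr <- g$Wr + tcrossprod(da_r, x)
    g$Ur <- g$Ur + tcrossprod(da_r, h_prev)
    g$Wc <- g$Wc + tcrossprod(da_c, x)
    g$Uc <- g$Uc + tcrossprod(dacr, h_prev)
    dX[t, ] <- drop(crossprod(params$Wu, da_u) + crossprod(params$Wr, da_r) +
                      crossprod(params$Wc, da_c))
    dh_carry <- dh * u + drop(crossprod(params$Uu, da_u) +
                                crossprod(params$Ur, da_r) +
                                crossprod(params$Uc, dacr))
  }
  list(grads = g, dX = dX, dh0 = dh_carry)
}

#' Gradients of a scalar loss through a GRU layer
#'
#' Runs the layer forward over `sequence`, evaluates `loss_fn` on the
#' emitted hidden-state matrix, and backpropagates through time. `loss_fn`
#' must return `list(value = <scalar>, grad = <T x hidden matrix>)`, the
#' gradient of the loss with respect to every hidden state. Correctness is
#' verified in the test suite against central finite differences.
#'
#' @param loss_fn differentiable loss on the hidden-state sequence.
#' @param sequence numeric matrix `T x input_size`.
#' @param params a [gru_layer_params()].
#' @param h0 initial state (default zero).
#' @return List with `value` (the loss), `grads` (list of six matrices
#'   matching `params`), `dX` and `dh0`.
#' @export
gru_gradients <- function(loss_fn, sequence, params, h0 = NULL) {
  fwd <- gru_layer_forward_cache(sequence, params, h0)
  l <- loss_fn(fwd$h)
  if (!is.finite(l$value))
    stop("gru_gradients: loss is not finite")
  bwd <- gru_layer_backward(fwd$cache, params, l$grad)
  c(list(value = l$value), bwd)
}
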