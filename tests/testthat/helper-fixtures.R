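# Shared fixtures: everything is generated in code at test time.

# A small labeled cohort: 4 subjects, 2 weeks, 2 with short episodes in the
# final (test) week.
tiny_cohort <- function(seed = 42, n_unhealthy = 2L) {
  generate_cohort(cohort_config(
    n_subjects = 4L, n_weeks = 2L, n_unhealthy_subjects = n_unhealthy,
    n_male = 2L,
    episode_spec = episode_spec(duration_range = c(6L, 12L))), seed = seed)
}

# A toy GRU-AE small enough for exhaustive/finite-difference checks.
toy_gru_ae <- function(hidden = c(3L, 2L, 3L), seed = 11) {
  gru_ae_params(2L, hidden, seed = seed)
}

# Single-layer scalar GRU with all six weights set to a constant.
scalar_gru <- function(w = 1) {
  p <- gru_layer_params(1L, 1L, seed = 1)
  for (nm in c("Wu", "Uu", "Wr", "Ur", "Wc", "Uc")) p[[nm]][] <- w
  p
}

# Central finite-difference gradient of f at x (vectorized over entries).
fd_gradient <- function(f, w, eps = 1e-5) {
  g <- w
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- w[i] + eps
    wm <- w; wm[i] <- w[i] - eps
    g[i] <- (f(wp) - f(wm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(pmax(abs(a), abs(b)), floor))
}

# Exhaustive pairwise AUC oracle: P(healthy outranks unhealthy), ties = 1/2,
# on healthiness scores (negated losses).
pairwise_auc <- function(losses, healthy) {
  hs <- -losses
  pos <- hs[healthy]
  neg <- hs[!healthy]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
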