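# gruae — GRU autoencoder health monitoring for vital-sign time series

`gruae` is an R package for unsupervised health monitoring of hourly
multivariate vital-sign streams — body temperature (°C) and heart rate
(bpm). It is aimed at researchers in digital health / physiological
time-series analysis who need a labeled-anomaly-free monitor plus a fully
reproducible synthetic benchmark to evaluate it on.

## The method

A three-layer **GRU autoencoder** (128 → 32 → 128 gated recurrent units,
no gate biases) with a fully connected sigmoid head is trained to
reproduce *healthy* signals only. Each layer updates its hidden state

```
u_t = σ(W_u x_t + U_u h_{t-1})          update gate
r_t = σ(W_r x_t + U_r h_{t-1})          reset gate
h̃_t = tanh(W x_t + r_t ⊙ (U h_{t-1}))   candidate state
h_t = u_t ⊙ h_{t-1} + (1 − u_t) ⊙ h̃_t
```

and the head reconstructs the input: `y_t = σ(W_y h³_t + b_y)`. Every
incoming hour is scored by its reconstruction error

```
Loss_t = ½ Σ_c (y_{t,c} − x_{t,c})²
```

which is compared to a threshold calibrated as the nearest-rank 99.5th
percentile of healthy training losses; exceeding hours raise health
alarms. A memoryless feedforward autoencoder with the same widths serves
as the baseline: it sees each hourly sample in isolation, so anomalies
that are only *contextually* wrong (a sustained mild fever at night, a
heart rate decoupled from the circadian phase) are invisible to it —
that contrast is the point of the comparison.

Evaluation follows the healthy-as-positive convention (TP = monitored
healthy and actually healthy), with TPR/FPR/accuracy from the confusion
matrix and AUC via the rank statistic
`AUC = (Σ ranks of healthy units − M(M+1)/2) / (M·N)` on negated losses,
ties averaged.

Because the 2000-subject cohort the method was originally evaluated on is
not deposited, the package ships a first-class simulator
(`generate_cohort()`): circadian sinusoid + Gaussian noise per channel,
healthy-labeled 1–2 h activity spikes (exercise), and short fever
episodes (37.0–38.0 °C, 65–169 bpm, 4–12 h) injected into a fixed number
of subjects in the test weeks. Everything is bit-reproducible from one
seed.

## Worked example

```r
library(gruae)

# 1. Simulate a small labeled cohort: 8 subjects, 3 weeks, 2 with episodes
cfg <- cohort_config(n_subjects = 8, n_weeks = 3, n_unhealthy_subjects = 2,
                     n_male = 4, seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> <vital_cohort: 8 subjects x 504 hours (full split), 4032 samples, 2 with episodes>

# 2. Chronological split (2 training weeks / 1 test week), normalize, window
sp <- chronological_split(cohort, train_weeks = 2)
norm <- fit_normalizer(sp$train)            # min-max to [0.1, 0.9]
windows <- cohort_windows(sp$train, norm)   # one-week training windows

# 3. Train the GRU-AE and the feedforward baseline
tc <- train_config(epochs = 300, seed = 42) # lr 0.01, Adam, batch 64
gru <- train_gru_ae(windows, tc)
ae  <- train_ae(windows, tc)

# 4. Calibrate a threshold on healthy training losses and monitor a subject
train_losses <- lapply(sp$train$subjects$subject_id, function(sid)
  monitor_stream(cohort_series(sp$train, sid),
                 monitor_config(gru, norm, threshold = 1))$losses)
thr <- calibrate_threshold(train_losses)    # 99.5th percentile -> 0.00174
mc <- monitor_config(gru, norm, thr, min_consecutive = 3)
sp$test$episodes
#>   subject_id start_hour end_hour
#> 1          3        106      111
#> 2          4         26       30
res <- monitor_stream(cohort_series(sp$test, 3), mc)
res$alarms
#>   subject_id hour_index        loss   threshold
#> 1          3        107 0.006190254 0.001737529
```

The monitor raises its alarm at hour 107 — one hour into subject 3's
injected episode (hours 106–111): the per-hour loss jumps more than
threefold above the calibrated threshold. `evaluate_models()` then
produces the paired per-subject/pooled AUC and subject-accuracy report
for both models on the same test cohort; with `min_consecutive = 3`,
1–2 hour exercise spikes are suppressed while multi-hour fevers alarm.

On a single small cohort the per-subject AUCs are noisy (two episodic
subjects); the package's benchmark — 40 subjects, 6 weeks, 10 with
episodes, full-width models, three seeds, run by
`tests/testthat/test-acceptance.R` — is the meaningful comparison. In
that benchmark the GRU-AE's mean per-subject AUC exceeds the feedforward
baseline's, which degrades sharply once unhealthy hours are marginally
plausible per sample.

A command-line wrapper is installed at `inst/cli/gruae`
(`simulate` / `train` / `monitor` / `evaluate`); see `?cli_main`.

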