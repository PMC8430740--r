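---
title: "Reconstruction-error health monitoring with a GRU autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-error health monitoring with a GRU autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The monitoring problem

`gruae` monitors hourly bivariate vital-sign streams — body temperature
(°C) and heart rate (bpm) — for signs of ill health, without labeled
anomalies. The idea is the classic autoencoder one: train a model to
reproduce *healthy* signals through a bottleneck, then score every incoming
hour by its reconstruction error

$$\mathrm{Loss}_t = \tfrac{1}{2}\sum_{c} (y_{t,c} - x_{t,c})^2 ,$$

where $x_t$ is the (normalized) observed sample and $y_t$ the model's
reconstruction. Hours whose loss exceeds a threshold calibrated on healthy
training data raise a health alarm.

Two models share this scoring rule:

* **GRU-AE** — a three-layer gated recurrent unit autoencoder
  (128 → 32 → 128 hidden units) with a fully connected sigmoid head. Each
  layer updates a hidden state from its input and its own previous state:
  $$u_t = \sigma(W_u x_t + U_u h_{t-1}), \quad
    r_t = \sigma(W_r x_t + U_r h_{t-1}),$$
  $$\tilde h_t = \tanh(W x_t + r_t \odot (U h_{t-1})), \quad
    h_t = u_t \odot h_{t-1} + (1 - u_t) \odot \tilde h_t .$$
  Note the gates carry no bias terms; only the output head
  $y_t = \sigma(W_y h^3_t + b_y)$ has a bias. The update-gate convention is
  exactly $h_t = u \odot h_{t-1} + (1-u) \odot \tilde h_t$ (some references
  swap $u$ and $1-u$). The candidate pre-activation applies the reset gate
  elementwise to the *product* $U h_{t-1}$, i.e.
  $\tanh(Wx + r \odot (Uh))$; the alternative reading
  $\tanh(Wx + U(r \odot h))$ differs only in where the gate multiplies,
  and the first reading is adopted throughout.
* **Feedforward AE baseline** — the same 128/32/128 widths applied to each
  hourly sample in isolation (input dimension 2, all sigmoid activations).
  It is deliberately memoryless: permuting the hours of a series permutes
  its losses identically, which is the property the comparison is designed
  to expose.

Because the output head is a sigmoid, raw signal units cannot be
reconstructed; channels are min–max scaled from their *training* range to
[0.1, 0.9], leaving margin before saturation. Test data are deliberately
**not clipped** to this band — anomalies may and should leave it.

## What the synthetic cohort emulates

The reference cohort design this package targets (2000 subjects aged
18–50, 978 male / 1022 female, 24 weeks of hourly sampling = 8,064,000
samples, weeks 1–20 training / 21–24 test, 613 subjects with
health-issue episodes) is not publicly deposited, so `generate_cohort()`
simulates it:

* **Healthy signal**: per channel, a mean level plus a 24-hour sinusoid
  (`amplitude * sin(2π(hour mod 24 − 8)/24)`) plus i.i.d. Gaussian noise.
  Defaults: 36.6 ± 0.4 °C circadian amplitude with 0.15 °C noise;
  72 ± 8 bpm with 3 bpm noise. These are ordinary resting ranges for
  healthy adults; the sinusoid is the simplest diurnal structure a
  sequence model can exploit and a memoryless model cannot.
* **Activity spikes**: Poisson-placed 1–2 h elevations (≈2 per week;
  +25–55 bpm, +0.2–0.6 °C) labeled *healthy* — exercise raises both
  signals and is the stated confounder a monitor must not flag.
* **Episodes**: exactly `n_unhealthy_subjects` subjects receive one
  contiguous fever bout with temperature drawn in 37.0–38.0 °C and heart
  rate in 65–169 bpm (both ranges exactly the span of the published
  unhealthy excerpts: unhealthy heart rates may stay normal — fever with
  bed rest — or spike), 1 h ramps at both ends, labeled *unhealthy*.
  Durations default to 4–12 h, matching the published unhealthy test-set
  excerpts, which are 5–6 hour intervals. Episodes are placed in the final
  test weeks by default so training data stay healthy-only (a flag allows
  otherwise, for robustness experiments only).
* **Reproducibility**: every subject draws from a pseudorandom stream
  derived from `(seed, subject_id)`, so cohorts are bit-identical for a
  given configuration and seed, regardless of generation order.

What the simulator does **not** model: subject-level heterogeneity in
baselines, weekday/weekend structure, sensor dropout and artifacts,
gradual onsets, or any physiologic coupling beyond the shared circadian
phase. Passing the synthetic benchmark therefore demonstrates that the
pipeline detects *contextual* anomalies in stationary periodic signals; it
is not evidence about messy real-world telemetry.

## Training and its numerical choices

Training minimizes the summed half-squared reconstruction error over
healthy windows. Defaults follow the reference protocol where stated
(learning rate 0.01, 4000 epochs, 128/32/128 units); the remaining choices
are the package's own:

* **Optimizer**: Adam at the reference learning rate (the robust default);
  `optimizer = "sgd"` gives literal fixed-rate gradient descent. Batch
  size defaults to 64 windows.
* **Training windows**: one week (168 h) per window, non-overlapping.
  Day-length windows were rejected after a design analysis: a model
  trained only on 24 h of state evolution from a zero state is never
  exposed to the state distribution that week-scale streaming visits, and
  its healthy-hour losses inflate once the monitor streams past the
  trained horizon. Week windows make the training condition match the
  monitoring condition (states start at zero at each window/stream start
  and cycle through full circadian periods).
* **Initialization**: uniform in ±sqrt(1/hidden_size), seeded; `h0 = 0` at
  every window start. The monitor carries state across hours within one
  subject and resets between subjects.
* **Precision**: the batched forward/backward pass runs in single
  precision (C++/RcppArmadillo) with double-precision master weights in R.
  A pure-R double-precision reference implementation of the same
  equations is validated against central finite differences (1e-4
  relative) and the float path against the reference (≈2e-5 observed);
  training tolerates float rounding by construction.
* **Divergence**: a non-finite epoch loss aborts with advice to lower the
  learning rate. Epoch losses are reported as mean per-timestep loss so
  curves are comparable across dataset sizes.

## Thresholding and the monitor

The deployed threshold is the nearest-rank 99.5th percentile
(`ceiling(q n)`-th order statistic) of pooled healthy training losses. The
reference method sweeps thresholds for ROC analysis but never states a
deployment rule, so the quantile rule is a declared design choice. With
`min_consecutive = 1` (the default, matching the per-sample reading) about
0.5% of healthy hours will exceed the threshold by construction; over a
672-hour test stream most subjects then see at least one false alarm, so
subject-level screening benefits from `min_consecutive = 3`, which also
suppresses 1–2 h exercise spikes while leaving multi-hour fevers
detectable. A subject is deemed unhealthy when at least one monitored hour
(after the run-length rule) is unhealthy.

## Evaluation conventions

All confusion-based metrics use the **healthy-as-positive** convention:
TP = monitored healthy and actually healthy, TN = monitored unhealthy and
actually unhealthy, TPR = TP/(TP+FN), FPR = FP/(FP+TN). The AUC uses the
rank statistic
$$AUC = \frac{\sum_{i \in \mathrm{healthy}} \mathrm{rank}_i - M(M+1)/2}{M\,N}$$
on healthiness scores (negated losses), with tied ranks averaged — mixing
conventions silently would flip AUC to 1−AUC, so the orientation is
asserted by tests against an exhaustive pairwise oracle and against the
trapezoidal area under the swept ROC. Per-subject AUC is computed only for
subjects whose test window contains both classes; healthy-only subjects
are excluded from the AUC mean and counted separately. Subject-level
accuracies are reported both overall and restricted to truly unhealthy
subjects, mirroring the reference's published counts (e.g. 1924/2000 →
96.2%, 581/613 → 94.8%, which the confusion arithmetic reproduces
exactly).

## The scaled-down benchmark

The reference's real-data results cannot be reproduced without its
cohort; the package instead fixes a desk-scale benchmark, run by the test
suite: 40 subjects, 6 weeks (5 training / 1 test), 10 subjects with fever
episodes, full-width 128/32/128 models, 300 epochs, three seeds
(101/202/303). The claim under test is directional: the GRU-AE's mean
per-subject AUC exceeds the feedforward AE's, and is at least 0.85. These
problem sizes were chosen so the whole suite trains both models three
times at full width on one CPU core in minutes while keeping enough test
hours (168 per subject) for stable within-subject ranking.

Two behaviors of streaming reconstruction monitors are worth knowing when
reading benchmark output. First, after a long anomaly the carried hidden
state needs hours to re-converge, so a burst of elevated losses can follow
an episode (a "hangover"); short bouts keep it negligible. Second, during
very long constant anomalies the state eventually adapts and
reconstruction improves — sustained-plateau anomalies are intrinsically
harder for stateful autoencoders than short contextual ones. Both effects
are structural properties of the method, not implementation artifacts.

## Known limitations

* Gate equations without biases follow the reference exactly; most modern
  GRU implementations include biases, so external weight imports will not
  round-trip.
* The simulator's labels are interval-valued by construction; the
  reference never specifies how clinician diagnoses map to per-hour
  labels, so episode-interval labeling is an explicit stand-in.
* Whether the reference's AE baseline consumed windows or single samples
  is unstated; the per-sample reading is adopted as the one consistent
  with its described insensitivity to time.
* `-ffast-math` is enabled for the compiled core; strict IEEE semantics
  are not preserved there (the double-precision R reference path is
  unaffected).
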