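---
title: "One-step-ahead SpO2 forecasting and hypoxemia prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step-ahead SpO2 forecasting and hypoxemia prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hypoxemia — blood oxygen saturation falling below a safe level — is common in
critically ill patients and drives mortality and organ injury. Pulse oximetry
(SpO2, in percent) is monitored continuously at the ICU bedside, so a model
that forecasts the SpO2 waveform even a few steps ahead gives clinicians a
window for intervention before a desaturation event, using no inputs beyond
the oximeter itself.

`swiftr` implements such a forecaster: a small LSTM network that predicts the
next SpO2 value from the two previous values, at a 5-minute and a 30-minute
horizon, together with the preprocessing, training protocol, and per-patient
evaluation machinery around it, and a synthetic ICU cohort simulator that
makes the whole pipeline testable without restricted clinical databases.

## The saturation transform

SpO2 values crowd against 100%, and clinically meaningful changes happen in a
narrow band. All modelling is therefore done on the transformed scale

$$p = 1 - \exp\!\left(\frac{\mathrm{SpO2} - 100}{10}\right),$$

which magnifies differences near 100% and maps 100% to 0. The transform is
strictly decreasing; its inverse is $\mathrm{SpO2} = 100 + 10\log(1-p)$.
Hypoxemia is operationalized as SpO2 below 92%, which on the transformed
scale is $p > 1 - e^{-0.8} \approx 0.55067$. Internally the full-precision
constant is used; 0.55067 is its five-decimal rounding. A value at exactly
92% is scored non-hypoxemic (strict inequality, configurable via
`include_boundary`).

## Preprocessing

Raw observation records may be irregular and gappy. The pipeline, in fixed
order:

1. **Regularization.** Each stay is resampled onto a uniform 5-minute grid
   from its first to last timestamp: each grid point takes the most recent
   valid observation at or before it (forward fill), and grid points before
   the first valid observation are backfilled with the first available
   value. The grid is anchored at the first timestamp so forward fill is
   always defined after the single leading backfill.
2. **Exclusion.** Stays that are entirely blank are dropped, as are stays
   with fewer than 61 grid points (five hours of 5-minute data, endpoints
   inclusive). The count is taken on the 5-minute grid, after
   regularization, before any downsampling.
3. **Transform** to the $p$ scale.
4. **Causal smoothing.** A window-5 causal moving average:
   $\mathrm{out}_i = \mathrm{mean}(x_{i-4},\dots,x_i)$. The first four points
   pass through unsmoothed — a full causal window does not yet exist. We read
   this rule literally (raw transformed values pass through); an
   expanding-window alternative is available via `partial = TRUE`. Causality
   means the filter is usable in real time, and truncating a series never
   changes earlier outputs.
5. **Downsampling** (30-minute horizon only): every 6th sample is kept,
   starting at the first, after smoothing at 5-minute resolution.

The smoothed series is rearranged into a supervised dataset: with $L$ lags
(default 2), rows $(p_{t-L},\dots,p_{t-1}) \to p_t$, giving $N - L$ rows for
an $N$-point series. Per-stay datasets are concatenated for training, so no
input window ever spans two stays; per-stay structure is kept for testing.

## The forecaster

Two architectures are provided: *shallow* — two LSTM hidden layers of 256
and 16 units — and *deep* — five layers, default widths 256, 128, 64, 32, 16
(the taper down to the shallow net's 16 is our choice; only the layer count
and first width are pinned down externally). Both start with a
batch-normalization input layer, place a dropout layer (ratio 0.1) after
every LSTM layer, and end in a single linear output neuron. The loss is mean
squared error, optimized with Adam.

Training runs for 100 epochs by default. Each epoch holds out a random 10%
validation split — re-drawn every epoch under `validation_mode =
"per_epoch"`, the literal protocol; a `"fixed"` mode draws the split once,
which makes best-epoch selection less noisy and is useful for small
datasets. After the last epoch the weights recorded at the epoch with the
lowest validation loss are restored.

Hyperparameters are selected by 3-fold cross-validation over the grid
{shallow, deep} × {0.001, 0.01, 0.1} (Adam learning rates), choosing the
lowest mean held-out MSE across folds. Fold assignment is at the pooled-row
level by default, matching the concatenated training vector; a stay-level
option (`by_stay = TRUE`) prevents within-stay leakage.

Prediction is one-step-ahead with teacher forcing: every prediction uses the
*observed* previous `lags` values, never previously predicted ones.
Predictions are clipped to the transform's image $[0, 1 - e^{-10}]$ so they
are always inverse-transformable.

### Engine implementation notes

The network engine is written in base R matrix operations: with lag windows
of 2–5 timesteps the BPTT unroll is short, and batched gate computations are
BLAS matrix products. Numerical choices:

* Gate order input/forget/cell/output; forget-gate bias initialized to 1;
  input-to-gate weights Glorot-uniform; recurrent weights orthogonal
  (sign-fixed QR for reproducibility).
* Batch normalization uses $\epsilon = 10^{-3}$ and momentum 0.99 for the
  running moments, computed over all batch × timestep elements of the scalar
  input; inference uses the running moments.
* Dropout is inverted dropout with an independent mask per element, active
  only during training.
* Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-7}$.
* All randomness (initialization, splits, shuffling, dropout) flows from the
  single config seed; runs are exactly reproducible single-threaded.

The analytic gradients are validated against central finite differences in
the test suite, and parameter counts against the closed-form LSTM formulas.
Non-finite training loss aborts with a diagnostic rather than continuing.

One empirical observation worth recording: with best-epoch restoration, an
aggressive learning rate of 0.1 is *not* reliably harmful for very small
networks (a handful of units) — the validation-restore step rescues it. The
expected ordering (0.001 beating 0.1) emerges at the real 256-unit width,
which is where the test suite checks it.

## Evaluation

Forecasts are thresholded exactly like the truth, yielding per-timepoint
labels. Per stay we report the confusion counts and accuracy, sensitivity,
specificity, PPV, plus waveform MSE and Pearson correlation on the $p$
scale. Undefined values are explicit `NA`s, never zeros: sensitivity is
undefined when a stay has no true events, specificity when all timepoints
are events, PPV when nothing was predicted positive, and the correlation
when either series is constant. Ground-truth labels are computed from the
smoothed, transformed series — the model's target space; a raw-label
sensitivity analysis is possible by thresholding the unsmoothed series.

Pooled results sum the per-stay counts; FPR = FP/(FP+TN) and FNR =
FN/(FN+TP). Distribution summaries use type-7 (linear-interpolation)
quantiles and Tukey whiskers at 1.5·IQR, with undefined values excluded and
the excluded count reported. Two statistical tests are wrapped: Welch's
unequal-variance t-test comparing hypoxemic-event counts between stays with
sensitivity below vs at least 0.5, and a Pearson chi-squared test (no
continuity correction) of independence between a two-level cohort label and
hypoxemic-timepoint counts.

## The synthetic cohort simulator

Real ICU oximetry databases are access-restricted, so the package ships a
seeded generator that emulates their structure: a per-stay baseline drawn
near 97% (SD 1.5, clipped at 100), transient desaturation events arriving as
a Poisson process (default 0.3/h), each a smooth dip of 5–25 percentage
points lasting 10–40 minutes (piecewise-exponential descent and recovery
with time constant duration/4; a triangular option exists), additive
Gaussian sensor noise (SD 0.5%), independent Bernoulli missingness (5%), and
either regular 5-minute sampling or geometric thinning tuned to a target
median inter-observation gap (25 minutes, emulating ward-style charting).
Stay lengths are log-normal around a 12-hour median, clamped to 6–24 hours.
Values are clipped to [0, 100] after summing baseline, events and noise.
Ground-truth event windows are recorded alongside each series.

These defaults were chosen once as clinically plausible test conditions:
event frequencies differ by an order of magnitude between real ventilated
and non-ventilated cohorts, so sub-population configs with different rates
are supported and the defaults sit in between. The generator emulates the
*statistical shape* of the data — baseline, dips, noise, missingness,
sampling — not the physiology: there is no gas-exchange model, no ventilator
feedback, no artifact structure (probe drops, motion spikes), and real
desaturations are not independent of one another. Passing tests on
synthetic cohorts therefore demonstrate that the machinery is correct and
that the forecaster can learn autocorrelated desaturation dynamics; they do
not certify performance numbers on real patients.

## Problem sizes in the test suite

The shipped tests run the full pipeline at reduced scale, a deliberate
package choice: cohorts of 8–20 stays with 6–12-hour median lengths, and
reduced-width networks (4–32 units per layer) trained for 5–80 epochs.
Properties that depend on the real architecture scale — the learning-rate
ordering in cross-validation — are checked at the full 256/16 shallow width
with a reduced epoch budget. The end-to-end acceptance check trains a
32/16-unit shallow model for 60 epochs on the default 20-stay synthetic
cohort and verifies that pooled sensitivity and PPV strictly exceed the
persistence baseline (predict the previous value), evaluated identically.

## Known limitations

* The forecaster is univariate by design; it cannot anticipate
  deteriorations with no precursor in the SpO2 trace itself.
* Per-epoch validation re-splitting makes the best-epoch choice noisy on
  small datasets; use `validation_mode = "fixed"` there.
* The simulator's independence assumptions (Poisson events, Bernoulli
  missingness) are simplifications; block missingness and event clustering
  in real data may interact with the forward-fill rule differently.
* Teacher-forced one-step prediction is the supported mode; recursive
  multi-step rollout is intentionally out of scope.
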