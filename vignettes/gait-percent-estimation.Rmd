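---
title: "Estimating continuous gait percent from a shank-worn IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating continuous gait percent from a shank-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

## The problem

Powered ankle prostheses and exoskeletons need to know where the leg is
inside the current gait cycle to act at the right moment — storing spring
energy in mid-stance, releasing it at push-off, setting the swing
trajectory. Event detectors that emit four to eight discrete labels leave
the controller blind between events, and online detectors add delay.
`gaitphase` estimates the *continuous* position in the cycle, the gait
percent y ∈ [0, 1), for every 10 ms sample of a six-channel IMU worn on
the lower shank, and forecasts it a configurable number of samples ahead
so that the control signal needs no detection delay at all.

The pipeline has four stages — segmentation, labeling, delay embedding,
regression — plus a synthetic-data generator that stands in for recorded
walking data. This vignette explains each stage's model, the parameters
that matter, the numerical conventions, and what the synthetic benchmark
does and does not demonstrate.

## Segmentation and percent labels

Ground truth comes from two force-sensitive resistors (FSRs) under heel
and toe. A heel strike is a rising crossing of a force threshold in the
heel channel; crossings closer than a refractory period to the previous
accepted one are discarded. Defaults: threshold = 50% of the channel
maximum (robust to unit-free FSR scales), refractory = 500 ms (no human
walks at more than two cycles per second per leg). Both are arguments of
`detect_heel_strikes()`. Non-finite samples are rejected as invalid
input; an empty or flat series yields zero events, not an error.

Cycles are half-open intervals `[IC, next IC)` in 1-based sample indices.
The half-open convention guarantees that consecutive cycles tile the
recording without overlap and that labels never reach 1. Cycles shorter
than 500 ms or longer than 2.5 s are discarded as segmentation outliers
(stumbles, recording edges); these bounds are arguments of
`segment_cycles()`. A cycle of fewer than two samples cannot carry a ramp
and is a degenerate-input error in `label_percent()`.

Within a cycle of n samples, sample i (0-based) is labeled
`y_i = i / n`. Labels are continuous by default; `quantize = TRUE` floors
them onto the 1% grid. We default to continuous labels because they are
strictly more informative and the quantized variant is recoverable from
them, while the reverse is not true. No resampling onto a fixed 100-point
grid is performed: the native 10 ms sampling is kept, so faster cadences
simply contribute fewer rows per cycle.

`build_percent_matrix()` stacks the six IMU channels (2 sensors × 3 axes)
for all retained cycles. The FSR channels are deliberately excluded from
the feature matrix — they exist to build the training labels, and a
deployed device would not carry them. All six IMU channels are used by
default; a `channels` argument restricts to a subset (e.g. the sagittal
gyro pair) since sagittal-plane rotation carries most of the phase
information during walking. `percent_to_phase()` maps continuous percents
onto the classical eight-phase nomenclature (half-open intervals, so the
preimages partition [0, 1) exactly) for applications that only need
coarse phases.

## The exponentially delayed embedding

A feed-forward network fed only the current sample cannot disambiguate
phases with similar instantaneous signals. The embedding therefore hands
it history: at anchor t the features are the current sample plus the
samples at past offsets

o ∈ {round(b^k) : k = 0, …, δ},

with base b = 1.6 and δ = 5 by default, i.e. offsets {1, 2, 3, 4, 7, 10}.
Short offsets resolve fast label changes; long offsets pin down the slow
cycle trend; the exponential spacing buys both with few inputs. The base
is a tunable real > 1 (`delay_config()`); `base = exp(1)` gives the
natural-exponential variant {1, 3, 7, 20} at δ = 3. Non-integer
exponentials are rounded to the sample grid and deduplicated — rounding
is the only sensible way to keep offsets addressable, and duplicates
carry no information.

Conventions, fixed once:

* Anchors run over t = d … T−1−f (0-based), so any valid configuration
  yields exactly T − d − f rows; `build_delayed_tensor()` (full window of
  d+1 samples) and `apply_exponential_window()` (sub-sampled) share this
  index range, which is what makes the column-selection equivalence
  between them exactly testable.
* The full delay length d defaults to 16 samples: it must contain the
  largest exponential offset (10 at the defaults) and a small margin for
  experimenting with slightly larger bases. `delay_config()` enforces
  `round(b^δ) ≤ d`.
* The current sample X[t] is always part of the feature vector — the
  model should see the present, not only the past.
* Targets are the strictly future labels y[t+1 … t+f] (forecasting is
  the point: the first output is 10 ms ahead). An ablation switch
  (`targets_ahead = FALSE`) starts targets at t instead.
* Windows may span a cycle boundary. The percent resets from ≈0.99 to 0
  there and the model has to learn that reset, so those rows are kept by
  default; `keep_boundary = FALSE` drops them for ablation.

With all six channels and the default window, the feature count is
k = (6 offsets + 1) × 6 channels = 42.

## The branched network

Each sensor's feature block (21 features at the defaults) feeds its own
branch of two 6-unit hidden layers with ReLU activations,
`a^l = max(0, θ^l a^{l-1} + b^l)`; the two branch outputs are
concatenated (order-preserving) and a single linear head maps the 12
concatenated units to the f outputs. Training one branch per sensor and
concatenating late keeps run-to-run variance low — the branches cannot
co-adapt across sensors early, and the head sees stable per-sensor
features. The head carries no hidden layers of its own; the capacity sits
in the branches. The output width equals the forecast horizon f, so the
default f = 1 recovers a one-unit output layer.

Training minimises the half-MSE cost `1/(2N) Σ‖ŷ−y‖²` (`mse_cost()`; the
½ cancels the gradient's factor 2). *Reported* errors use the standard
MSE without the ½ (`mse_metric()`) — keeping the two scales separate
avoids a silent factor-2 ambiguity when comparing numbers. Details fixed
by choice, all configurable in `fit_edfnn()`:

* Optimizer Adam, learning rate 1e-3, 200 epochs, minibatch 256 —
  unremarkable defaults that converge well inside the benchmark's error
  regime; plain SGD is available.
* Scaled uniform initialisation, `U(±1/√fan_in)` per layer, biases zero,
  drawn from the run seed.
* Per-feature-column standardisation using the *training split's*
  mean/sd, stored in the fitted model and re-applied to any prediction
  input, so the validation split never leaks into normalisation.
* The output layer is linear (this is regression); estimates are clamped
  into [0, 1) only at forecast/evaluation time, never during training —
  clamping inside training would zero gradients at the boundary.
* Reproducibility is a contract: the same seed yields bitwise-identical
  parameters and learning curves (R-side seeded initialisation, a seeded
  Mersenne-Twister batch shuffler in the compiled core).
* A cost that turns non-finite aborts the run with an error naming the
  epoch; the repeated-run driver records such failures per run instead of
  dying.

The forward/backward pass and the training loop are hand-written in
RcppArmadillo; a plain-R forward pass (`forward_edfnn()`, `relu()`,
`layer_forward()`, `concat_branches()`) provides an independent route
that the test suite checks against the compiled path, alongside a
central-finite-difference gradient check (at a generic parameter point —
ReLU is not differentiable at 0, so checks avoid placing pre-activations
exactly on the kink).

## Evaluation protocol

Splits are by whole gait cycles, never mid-cycle: a seeded shuffle
assigns 80% of cycles to training. Splitting embedded rows by the cycle
of their *anchor* keeps every window temporally coherent; rows near a
validation-cycle edge may still contain a few samples from a neighbouring
training cycle inside their past window — an accepted, standard amount of
leakage for windowed time-series splits, and far smaller than splitting
mid-cycle would cause. Metrics (MSE, MAE, R² for both splits;
`to_percent()` for the ×100 percent-of-cycle scale) are row-order
invariant and clamp predictions into [0, 1) by default (switchable).

`run_experiment()` repeats split + train + evaluate over seeded runs for
any named collection of datasets (per subject, joined) and returns the
per-run rows; `tidy()` gives mean ± sd per dataset, `glance()` a one-line
summary, `autoplot()` the distribution view. 10 runs is the fast
protocol used throughout the tests; 100 runs reproduces a full
distribution picture at ten times the cost.

Joined multi-subject datasets are built by embedding each subject
separately and concatenating the embedded rows (`join_embeddings()`), so
no window ever mixes two subjects' signals.

## The synthetic benchmark

There is no public dataset for this task, so the generator produces what
the method assumes: periodic, phase-informative, subject-varying
multichannel signals.

* Each IMU channel is a fixed sum of 2–4 harmonics of the cycle
  frequency; the sagittal gyro carries the dominant swing peak at phase
  0.7. Harmonic sums — not biomechanical simulation — because the
  algorithm under test only needs waveforms whose shape identifies the
  phase; their anatomical fidelity is irrelevant to what is being
  verified.
* FSR contact: heel active on phase [0, 0.40), toe on [0.10, 0.60).
  Stance (any FSR active) is therefore exactly the first 60% of the
  cycle, matching the physiological 60/40 stance–swing split, with heel
  contact onset defining phase 0 and toe-off at 60%. FSRs are noiseless
  rectangles so they remain an exact segmentation reference.
* Per-cycle durations are drawn from cadence 1.0 s ± 5%; channel noise
  is white with sd = 2% of each channel's peak amplitude. These two
  numbers set the benchmark's difficulty and are deliberately not free
  knobs of the experiments: they are the fixed study conditions under
  which the error regime is assessed.
* Subjects differ by per-channel gain multipliers (uniform in
  [0.8, 1.25]) and small waveform phase shifts (±0.04 cycles), drawn
  deterministically from the benchmark seed — enough heterogeneity that
  the joined dataset is genuinely harder to validate on than a single
  subject, which the test suite asserts directionally.
* A 15° incline is modeled as a gain/offset perturbation of the
  accelerometer and sagittal-gyro channels; walking speed is carried as
  profile metadata only.

What passing tests on this benchmark shows: the segmentation is exact on
clean contact signals, the embedding algebra is correct, the network
trains stably to the intended error regime, and the whole pipeline is
reproducible. What it does not show: robustness to real IMU artifacts
(drift, soft-tissue wobble, sensor re-mounting), to FSR degradation, to
pathological or amputee gait asymmetry, or to outdoor speed variation —
real recordings are noisier and less stationary than harmonic sums with
white noise, so real-data errors should be expected to be higher.

## Problem sizes

The experiments the package runs on itself use 250 cycles per subject
(~25,000 samples), 8 subjects for the joined benchmark (~200,000 embedded
rows), and 10 seeded runs per configuration; smaller property tests use
tens of cycles. These sizes keep a full pipeline verification in the
minutes range on one CPU while remaining in the same order of magnitude
as a realistic multi-subject session.

## Known limitations

* Offline batch method: no streaming segmentation or incremental
  training.
* The generator does not model treadmill-vs-overground differences,
  shoe conditions, or magnetometer channels.
* Single IMU placement (lower shank) is assumed throughout.
* Forecast horizons beyond a few samples degrade gracefully but are
  untested beyond f ≈ 5; the architecture caps at the information in a
  16-sample window.
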