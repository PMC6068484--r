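# gaitphase

Continuous gait-percent estimation from a single shank-worn inertial
measurement unit (IMU), for researchers working on gait analysis and the
control of powered lower-limb prostheses and exoskeletons.

Classical gait-event detectors label a handful of discrete events (initial
contact, foot flat, heel off, toe off). That granularity is too coarse to
control an active ankle: the actuator needs to know *where inside the
cycle* the leg is, continuously. `gaitphase` instead treats the gait cycle
as a continuous percentage. Every 10 ms sample of a walking recording is
labeled with its position y ∈ [0, 1) inside the current heel-strike-to-
heel-strike cycle (1% resolution or finer), and a small neural network
learns to estimate — and forecast — that percentage from the six IMU
channels alone. Force-sensitive resistors (FSRs) under heel and toe are
used only as the ground-truth segmentation reference and never enter the
model input.

## Method

1. **Segmentation.** Heel strikes are rising threshold crossings of the
   heel FSR with a refractory period (default 500 ms). Each consecutive
   pair of strikes bounds one half-open cycle `[IC, next IC)`; sample *i*
   of a cycle of *n* samples gets the label `y_i = i / n`.
2. **Exponentially delayed embedding.** The input at anchor time *t* is
   the current sample plus the past samples at offsets
   `{round(b^k) : k = 0..δ}` — by default base b = 1.6 and δ = 5, giving
   offsets {1, 2, 3, 4, 7, 10}. The window is dense near the present
   (fast label changes) and sparse in the past (cycle trend), emulating
   what a recurrent network learns to attend to at a fraction of the
   compute. With 6 channels this yields k = (6 + 1) × 6 = 42 features.
3. **Branched feed-forward network.** Each sensor (gyroscope,
   accelerometer) feeds its own branch of two 6-unit ReLU hidden layers
   (`a^l = σ(θ^l a^{l-1} + b^l)`); the branch outputs are concatenated and
   a linear head produces the f forecast outputs (default f = 1, the
   percent 10 ms ahead — so a controller acts with no detection delay).
   Training minimises the half-MSE cost `1/(2N) Σ‖ŷ−y‖²` with minibatch
   Adam (lr 1e-3, batch 256, 200 epochs), via a hand-written
   backpropagation core in RcppArmadillo.
4. **Evaluation.** MSE, MAE and R² on the normalized percent scale
   (`MSE% = 100·MSE`, `MAE% = 100·MAE`), computed on cycle-level 80/20
   train/validation splits, repeated over seeded runs to report
   mean ± sd.

No public dataset accompanies the method, so the package ships a synthetic
multi-subject walking generator (`simulate_recording()`,
`simulate_benchmark()`): harmonic-sum IMU waveforms with a dominant
sagittal-gyro swing peak, 60/40 stance–swing FSR contact structure, 5%
cadence jitter and 2% channel noise. Every stage of the pipeline is tested
against it.

## Worked example

```r
library(gaitphase)

rec <- simulate_recording(subject_profile(), n_cycles = 250, seed = 1)
emb <- embed_recording(rec)          # segment + label + embed
emb
#> <gait_embedding> 24905 rows x 42 features (exponential window), f = 1, 249 cycles

parts <- split_by_cycles(emb, fraction = 0.8, seed = 1)
fit <- fit_edfnn(parts$train, validation = parts$validation, seed = 1)
fit
#> <edfnn> 2 branch(es) x hidden [6, 6], f = 1, adam lr 0.001, 200 epochs
#>   final train cost 6.83e-05, val cost 1.73e-05

evaluate_edfnn(fit, parts$train, parts$validation)
#> # A tibble: 1 × 6
#>      t_mse     v_mse   t_mae   v_mae  t_r2  v_r2
#>      <dbl>     <dbl>   <dbl>   <dbl> <dbl> <dbl>
#> 1 0.000137 0.0000345 0.00457 0.00425 0.998 1.000
```

A validation MSE of 3.5e-5 on the [0, 1) scale means the estimate is off
by about 0.6% of the gait cycle on a typical sample (v_mae 0.00425 →
0.43% via `to_percent()`), and R² ≈ 1 says the prediction tracks the
sawtooth ground truth almost perfectly on this low-noise synthetic
subject. Forecasting one step (10 ms) ahead from the newest window:

```r
forecast_percent(fit, parts$validation$X[1, ])
#>            [,1]
#> [1,] 0.01445988     # true next label: 0.01041667
```

`autoplot()` methods exist for recordings, labeled datasets (the percent
sawtooth), fitted models (learning curve) and repeated-run experiments.
A command-line wrapper with `simulate` / `segment` / `embed` / `train` /
`predict` / `evaluate` subcommands is installed under `inst/cli/gaitphase`.

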