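#' Describe a synthetic walking subject
#'
#' A subject profile holds the per-subject parameters of the synthetic
#' walking-signal generator: mean cycle duration and its variability,
#' per-channel amplitude gains, additive noise level, and the walking
#' condition (speed, incline). Profiles are deterministic containers;
#' all randomness enters through the seed of [simulate_recording()].
#'
#' @param subject_id Character identifier for the subject.
#' @param cadence_mean Mean gait-cycle duration in seconds. Default 1.0 s
#'   (100 samples at the 10 ms sampling period).
#' @param cadence_std Standard deviation of per-cycle duration in seconds.
#'   Default 0.05 s (5% jitter).
#' @param channel_gains Named numeric vector of amplitude gains for the six
#'   IMU channels `gx, gy, gz` (gyroscope, deg/s) and `ax, ay, az`
#'   (accelerometer, g).
#' @param channel_phase Named numeric vector of small per-channel phase
#'   shifts (fraction of a cycle) that vary waveform morphology between
#'   subjects. Default all zero.
#' @param noise_std Additive white-noise standard deviation, as a fraction
#'   of each channel's peak amplitude. Default 0.02 (2%).
#' @param speed Walking speed in m/s (metadata; 2.2--3.8 treadmill range).
#' @param incline Surface inclination in degrees (0 or 15). A non-zero
#'   incline perturbs the accelerometer offsets and the sagittal gyro gain.
#'
#' @return An object of class `subject_profile`.
#' @export
#' @examples
#' subject_profile("S1", cadence_mean = 1.1, noise_std = 0.01)
subject_profile <- function(subject_id = "S1",
                            cadence_mean = 1.0,
                            cadence_std = 0.05,
                            channel_gains = c(gx = 150, gy = 180, gz = 120,
                                              ax = 0.6, ay = 0.5, az = 0.8),
                            channel_phase = c(gx = 0, gy = 0, gz = 0,
                                              ax = 0, ay = 0, az = 0),
                            noise_std = 0.02,
                            speed = 2.6,
                            incline = 0) {
  stopifnot(cadence_mean > 0, cadence_std >= 0, noise_std >= 0,
            speed > 0, incline >= 0)
  chans <- c("gx", "gy", "gz", "ax", "ay", "az")
  if (!all(chans %in% names(channel_gains))) {
    stop("`channel_gains` must name all six IMU channels", call. = FALSE)
  }
  if (!all(chans %in% names(channel_phase))) {
    stop("`channel_phase` must name all six IMU channels", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id,
         cadence_mean = cadence_mean,
         cadence_std = cadence_std,
         channel_gains = channel_gains[chans],
         channel_phase = channel_phase[chans],
         noise_std = noise_std,
         speed = speed,
         incline = incline),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile> ", x$subject_id,
      sprintf(" cadence %.2f s +- %.0f%%, noise %.0f%%, %g m/s, %g deg\n",
              x$cadence_mean, 100 * x$cadence_std / x$cadence_mean,
              100 * x$noise_std, x$speed, x$incline))
  invisible(x)
}

# Unit-amplitude harmonic waveform for one channel at gait phase p in [0, 1).
# Each channel is a small sum of harmonics of the cycle frequency; the
# sagittal gyro channel (gy) carries the dominant swing peak at phase 0.7.
.template_base <- function(channel, p) {
  switch(channel,
    gx = 0.6 * sin(2 * pi * p) + 0.3 * cos(4 * pi * p + 0.5),
    gy = cos(2 * pi * (p - 0.7)) + 0.4 * cos(4 * pi * (p - 0.7)),
    gz = 0.8 * sin(2 * pi * (p - 0.2)) + 0.5 * sin(4 * pi * (p - 0.05)) +
      0.2 * sin(6 * pi * p),
    ax = 0.5 * cos(2 * pi * p) + 0.4 * cos(4 * pi * (p - 0.6)) +
      0.15 * cos(6 * pi * (p - 0.3)),
    ay = 0.7 * sin(2 * pi * (p - 0.35)) + 0.25 * cos(6 * pi * p),
    az = 1 + 0.3 * cos(2 * pi * (p - 0.1)) + 0.3 * cos(4 * pi * (p - 0.8)),
    stop("unknown channel ", channel, call. = FALSE)
  )
}

#' Evaluate the noiseless cycle template of a subject
#'
#' Returns the deterministic waveform value of every sensor channel at the
#' requested gait phases: six smooth 1-periodic IMU channels (sums of two to
#' four harmonics, with the dominant sagittal-gyro swing peak near phase
#' 0.7) and two rectangular FSR contact channels. Heel contact onset defines
#' phase 0; the heel FSR is active on phase \eqn{[0, 0.40)} (heel-off at
#' 40%), the toe FSR on \eqn{[0.10, 0.60)} (toe-off at 60%), so the stance
#' phase -- any FSR active -- covers exactly the first 60% of the cycle.
#'
#' @param phase Numeric vector of gait phases, each in `[0, 1)`.
#' @param profile A [subject_profile()].
#' @return A tibble with one row per phase and columns
#'   `gx, gy, gz, ax, ay, az, fsr_heel, fsr_toe`.
#' @export
#' @examples
#' tpl <- cycle_template(c(0, 0.3, 0.65), subject_profile())
#' tpl$fsr_heel   # heel in contact at phase 0 and 0.3, airborne at 0.65
cycle_template <- function(phase, profile) {
  stopifnot(inherits(profile, "subject_profile"))
  if (any(!is.finite(phase)) || any(phase < 0) || any(phase >= 1)) {
    stop("`phase` must lie in [0, 1)", call. = FALSE)
  }
  chans <- c("gx", "gy", "gz", "ax", "ay", "az")
  tilt <- profile$incline / 15  # incline as a fraction of the 15-degree case
  out <- lapply(chans, function(ch) {
    p <- (phase - profile$channel_phase[[ch]]) %% 1
    v <- .template_base(ch, p) * profile$channel_gains[[ch]]
    # incline modelled as a gain/offset perturbation of the template
    if (tilt > 0) {
      if (ch == "gy") v <- v * (1 + 0.1 * tilt)
      if (ch == "ax") v <- v + 0.10 * tilt * profile$channel_gains[[ch]]
      if (ch == "az") v <- v - 0.05 * tilt * profile$channel_gains[[ch]]
    }
    v
  })
  names(out) <- chans
  out$fsr_heel <- as.numeric(phase < 0.40)
  out$fsr_toe <- as.numeric(phase >= 0.10 & phase < 0.60)
  tibble::as_tibble(out)
}

# Peak absolute amplitude of each clean IMU channel over one cycle,
# used to scale the additive noise.
.channel_amplitudes <- function(profile) {
  grid <- seq(0, 1 - 1e-4, by = 1e-3)
  tpl <- cycle_template(grid, profile)
  vapply(tpl[, c("gx", "gy", "gz", "ax", "ay", "az")],
         function(v) max(abs(v)), numeric(1))
}

#' Simulate one walking recording
#'
#' Concatenates `n_cycles` gait cycles with per-cycle durations drawn from
#' the profile's cadence distribution, sampled at the 10 ms period, and adds
#' seeded white noise to the IMU channels (`noise_std` of each channel's
#' peak amplitude). The FSR channels are noiseless and rectangular so they
#' serve as an exact ground-truth contact reference. The true heel-strike
#' onset indices and the true continuous phase of every sample are attached
#' as attributes.
#'
#' @param profile A [subject_profile()].
#' @param n_cycles Number of gait cycles to generate (>= 2).
#' @param seed Integer seed; the same seed reproduces the recording exactly.
#' @return A tibble of class `gait_recording` with columns
#'   `t` (1-based sample index, 10 ms period),
#'   `gx, gy, gz` (deg/s), `ax, ay, az` (g), `fsr_heel, fsr_toe`,
#'   and attributes `true_onsets` (integer sample indices of heel strikes),
#'   `true_phase` (per-sample phase), `profile`, `sample_ms`.
#' @export
#' @examples
#' rec <- simulate_recording(subject_profile(), n_cycles = 5, seed = 1)
#' attr(rec, "true_onsets")
simulate_recording <- function(profile, n_cycles, seed = 1) {
  stopifnot(inherits(profile, "subject_profile"), n_cycles >= 2)
  withr::with_seed(seed, {
    mean_len <- profile$cadence_mean * 100      # samples at 10 ms
    sd_len <- profile$cadence_std * 100
    len <- round(rnorm(n_cycles, mean_len, sd_len))
    len <- pmax(len, 20L)                       # guard degenerate draws
    onsets <- c(1L, 1L + cumsum(len[-n_cycles]))
    phase <- unlist(lapply(len, function(L) (seq_len(L) - 1) / L),
                    use.names = FALSE)
    tpl <- cycle_template(phase, profile)
    amp <- .channel_amplitudes(profile)
    n <- length(phase)
    for (ch in names(amp)) {
      tpl[[ch]] <- tpl[[ch]] + rnorm(n, sd = profile$noise_std * amp[[ch]])
    }
    rec <- tibble::tibble(t = seq_len(n)) |> dplyr::bind_cols(tpl)
    structure(rec,
              true_onsets = as.integer(onsets),
              true_phase = phase,
              profile = profile,
              sample_ms = 10,
              class = c("gait_recording", class(rec)))
  })
}

#' Generate a multi-subject synthetic walking benchmark
#'
#' Creates `n_subjects` recordings with distinct subject profiles (varying
#' channel gains and waveform phase shifts around the default morphology)
#' plus the joined collection, emulating a multi-subject walking dataset.
#' Per-subject gain multipliers are drawn uniformly in \[0.8, 1.25\] and
#' per-channel phase shifts in \[-0.04, 0.04\] cycles, deterministically
#' from `seed`.
#'
#' @param n_subjects Number of subjects (>= 1). Default 8.
#' @param cycles_per_subject Gait cycles per subject (>= 2). Default 250.
#' @param seed Integer seed controlling both the profile draw and every
#'   recording.
#' @param profiles Optional list of [subject_profile()]s overriding the
#'   generated ones (length `n_subjects`).
#' @return An object of class `gait_benchmark`: a list with elements
#'   `recordings` (named list of `gait_recording`) and `profiles`.
#' @export
#' @examples
#' bench <- simulate_benchmark(n_subjects = 2, cycles_per_subject = 5, seed = 1)
#' names(bench$recordings)
simulate_benchmark <- function(n_subjects = 8, cycles_per_subject = 250,
                               seed = 1, profiles = NULL) {
  stopifnot(n_subjects >= 1, cycles_per_subject >= 2)
  if (is.null(profiles)) {
    profiles <- withr::with_seed(seed, {
      lapply(seq_len(n_subjects), function(i) {
        gains <- c(gx = 150, gy = 180, gz = 120,
                   ax = 0.6, ay = 0.5, az = 0.8) * runif(6, 0.8, 1.25)
        shifts <- runif(6, -0.04, 0.04)
        names(shifts) <- c("gx", "gy", "gz", "ax", "ay", "az")
        subject_profile(subject_id = sprintf("S%d", i),
                        channel_gains = gains,
                        channel_phase = shifts)
      })
    })
  }
  stopifnot(length(profiles) == n_subjects)
  recordings <- purrr::imap(profiles, function(pr, i) {
    simulate_recording(pr, cycles_per_subject, seed = seed + 7919L * i)
  })
  names(recordings) <- vapply(profiles, `[[`, character(1), "subject_id")
  structure(list(recordings = recordings, profiles = profiles),
            class = "gait_benchmark")
}

#' @export
print.gait_benchmark <- function(x, ...) {
  cat("<gait_benchmark>", length(x$recordings), "subjects,",
      sum(vapply(x$recordings,
                 function(r) length(attr(r, "true_onsets")), numeric(1))),
      "cycles total\n")
  invisible(x)
}

#' Write a recording and its ground truth to plain-text files
#'
#' Writes the recording as a CSV with header
#' `t,gx,gy,gz,ax,ay,az,fsr_heel,fsr_toe` (one row per 10 ms sample) plus a
#' truth sidecar CSV holding the true heel-strike onsets and per-sample
#' phases, for external tools and round-trip tests.
#'
#' @param recording A `gait_recording`.
#' @param path Output CSV path; the sidecar is written to
#'   `<path>.truth.csv`.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "gait_recording"))
  utils::write.csv(as.data.frame(recording), path, row.names = FALSE)
  truth <- data.frame(t = recording$t,
                      phase = attr(recording, "true_phase"),
                      is_onset = recording$t %in% attr(recording, "true_onsets"))
  utils::write.csv(truth, paste0(path, ".truth.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a recording CSV written by [write_recording_csv()]
#'
#' @param path CSV path with header `t,gx,gy,gz,ax,ay,az,fsr_heel,fsr_toe`.
#' @return A `gait_recording` tibble (without generator truth attributes
#'   unless the sidecar is present, in which case they are restored).
#' @export
read_recording_csv <- function(path) {
  rec <- tibble::as_tibble(utils::read.csv(path))
  need <- c("t", "gx", "gy", "gz", "ax", "ay", "az", "fsr_heel", "fsr_toe")
  if (!all(need %in% names(rec))) {
    stop("recording CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  sidecar <- paste0(path, ".truth.csv")
  out <- structure(rec, sample_ms = 10,
                   class = c("gait_recording", class(rec)))
  if (file.exists(sidecar)) {
    truth <- utils::read.csv(sidecar)
    attr(out, "true_phase") <- truth$phase
    attr(out, "true_onsets") <- as.integer(truth$t[truth$is_onset])
  }
  out
}
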