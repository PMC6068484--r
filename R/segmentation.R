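#' Detect heel-strike events in an FSR force channel
#'
#' Finds rising crossings of a force threshold in the heel FSR signal and
#' applies a refractory rule: any crossing closer than `min_cycle_ms` to the
#' previously accepted one is discarded. A sample counts as a rising
#' crossing when it is at or above the threshold and the previous sample is
#' below it (the very first sample counts if it starts at or above the
#' threshold).
#'
#' @param x A `gait_recording` (its `fsr_heel` column is used) or a numeric
#'   force series, arbitrary units >= 0.
#' @param threshold Force threshold (> 0). Default: 50% of the channel
#'   maximum.
#' @param min_cycle_ms Refractory period in milliseconds. Default 500 ms.
#' @param sample_ms Sampling period in milliseconds. Default 10 ms.
#' @return Sorted integer vector of 1-based event sample indices (empty for
#'   an all-zero or empty series).
#' @export
#' @examples
#' fsr <- rep(c(1, 1, 0, 0, 0), 4)   # contact pulses every 50 ms
#' detect_heel_strikes(fsr, threshold = 0.5, min_cycle_ms = 30)
detect_heel_strikes <- function(x, threshold = NULL, min_cycle_ms = 500,
                                sample_ms = 10) {
  if (inherits(x, "gait_recording")) x <- x$fsr_heel
  x <- as.numeric(x)
  if (length(x) == 0) return(integer(0))
  if (any(!is.finite(x))) {
    stop("invalid signal: FSR series contains non-finite values",
         call. = FALSE)
  }
  stopifnot(min_cycle_ms > 0, sample_ms > 0)
  if (is.null(threshold)) {
    threshold <- 0.5 * max(x)
    if (threshold <= 0) return(integer(0))   # flat series: no crossings
  }
  stopifnot(threshold > 0)
  rising <- which(x >= threshold & c(TRUE, x[-length(x)] < threshold))
  if (length(rising) == 0) return(integer(0))
  min_gap <- min_cycle_ms / sample_ms
  keep <- rising[1]
  last <- rising[1]
  for (i in rising[-1]) {
    if (i - last >= min_gap) {
      keep <- c(keep, i)
      last <- i
    }
  }
  as.integer(keep)
}

#' Cut a recording into gait cycles at heel-strike events
#'
#' Each consecutive event pair `[e_i, e_{i+1})` becomes one half-open cycle
#' segment. Cycles shorter than `min_duration_ms` or longer than
#' `max_duration_ms` are discarded as outliers so the percent sawtooth stays
#' well formed.
#'
#' @param recording A `gait_recording` (or any data frame with as many rows
#'   as the recording has samples).
#' @param events Sorted ascending integer vector of heel-strike sample
#'   indices, all within the recording.
#' @param min_duration_ms,max_duration_ms Retained cycle duration bounds in
#'   milliseconds. Defaults 500 and 2500 ms.
#' @param sample_ms Sampling period in milliseconds. Default 10 ms.
#' @return A tibble with one row per retained cycle: `cycle` (id), `start`
#'   (first sample, 1-based), `end` (one past the last sample), `duration`
#'   (samples). Fewer than 2 events yield an empty tibble.
#' @export
#' @examples
#' rec <- simulate_recording(subject_profile(), n_cycles = 4, seed = 1)
#' segment_cycles(rec, detect_heel_strikes(rec))
segment_cycles <- function(recording, events, min_duration_ms = 500,
                           max_duration_ms = 2500, sample_ms = 10) {
  n <- nrow(recording)
  events <- as.integer(events)
  if (is.unsorted(events, strictly = TRUE)) {
    stop("`events` must be strictly ascending", call. = FALSE)
  }
  if (length(events) > 0 && (min(events) < 1 || max(events) > n)) {
    stop("`events` must lie within the recording", call. = FALSE)
  }
  if (length(events) < 2) {
    return(tibble::tibble(cycle = integer(0), start = integer(0),
                          end = integer(0), duration = integer(0)))
  }
  out <- tibble::tibble(
    start = events[-length(events)],
    end = events[-1]
  ) |>
    dplyr::mutate(duration = .data$end - .data$start) |>
    dplyr::filter(.data$duration >= min_duration_ms / sample_ms,
                  .data$duration <= max_duration_ms / sample_ms) |>
    dplyr::mutate(cycle = dplyr::row_number(), .before = 1)
  out
}

#' Continuous gait-percent labels for one cycle
#'
#' Sample `i` (0-based within the cycle) receives
#' \eqn{y_i = i / \mathrm{duration} \in [0, 1)}; with `quantize = TRUE` the
#' label is floored onto the 1% grid,
#' \eqn{\lfloor 100 i / \mathrm{duration}\rfloor / 100}.
#'
#' @param duration Cycle duration in samples (>= 2), or a one-row cycle
#'   tibble from [segment_cycles()].
#' @param quantize Quantize labels to 1% bins. Default `FALSE` (continuous).
#' @return Numeric vector of length `duration`, strictly within `[0, 1)`.
#' @export
#' @examples
#' label_percent(100)[c(1, 51, 100)]   # 0, 0.5, 0.99
label_percent <- function(duration, quantize = FALSE) {
  if (is.data.frame(duration)) duration <- duration$duration
  stopifnot(length(duration) == 1)
  if (!is.finite(duration) || duration < 2) {
    stop("degenerate cycle: duration must be >= 2 samples", call. = FALSE)
  }
  i <- seq_len(duration) - 1
  y <- i / duration
  if (quantize) y <- floor(100 * i / duration) / 100
  y
}

#' Stack cycle samples into a percent-labeled sensor dataset
#'
#' Builds the per-sample design matrix for the learning stages: the six IMU
#' channels (2 sensors x 3 axes), row per sample over all retained cycles,
#' paired with continuous gait-percent labels. The FSR channels are the
#' segmentation reference only and are excluded from the output features.
#'
#' @param recording A `gait_recording`.
#' @param cycles Cycle tibble from [segment_cycles()]; cycles must be
#'   non-overlapping and within the recording.
#' @param quantize Passed to [label_percent()].
#' @param channels IMU channels to keep. Default all six; a subset (e.g.
#'   `c("gy", "gz")` for the sagittal gyro pair) restricts the feature set.
#' @return A tibble of class `gait_samples` with columns `t` (original
#'   sample index), `cycle`, `percent`, and one column per selected channel.
#'   An empty cycle tibble yields an empty dataset.
#' @export
#' @examples
#' rec <- simulate_recording(subject_profile(), n_cycles = 4, seed = 1)
#' cyc <- segment_cycles(rec, detect_heel_strikes(rec))
#' build_percent_matrix(rec, cyc)
build_percent_matrix <- function(recording, cycles, quantize = FALSE,
                                 channels = c("gx", "gy", "gz",
                                              "ax", "ay", "az")) {
  stopifnot(all(channels %in% c("gx", "gy", "gz", "ax", "ay", "az")))
  if (nrow(cycles) == 0) {
    out <- tibble::tibble(t = integer(0), cycle = integer(0),
                          percent = numeric(0))
    for (ch in channels) out[[ch]] <- numeric(0)
    return(structure(out, channels = channels,
                     class = c("gait_samples", class(out))))
  }
  if (any(cycles$end[-nrow(cycles)] > cycles$start[-1])) {
    stop("`cycles` must be non-overlapping and ordered", call. = FALSE)
  }
  if (min(cycles$start) < 1 || max(cycles$end) > nrow(recording) + 1) {
    stop("`cycles` must lie within the recording", call. = FALSE)
  }
  rows <- purrr::pmap(cycles, function(cycle, start, end, duration, ...) {
    idx <- start:(end - 1)
    tibble::tibble(t = idx, cycle = cycle,
                   percent = label_percent(duration, quantize = quantize))
  })
  out <- dplyr::bind_rows(rows)
  sig <- tibble::as_tibble(recording)[out$t, channels, drop = FALSE]
  out <- dplyr::bind_cols(out, sig)
  structure(out, channels = channels,
            class = c("gait_samples", class(out)))
}

#' Names of the eight classical gait phases
#'
#' Labels 0--7 of the standard eight-phase subdivision of the gait cycle,
#' with their percentage intervals (half-open).
#' @return A tibble with columns `label`, `phase`, `lo`, `hi`.
#' @export
gait_phase_table <- function() {
  tibble::tibble(
    label = 0:7,
    phase = c("Initial Contact", "Mid-stance (FF)", "Terminal Mid-stance (FF)",
              "Push Off", "Pre-swing", "Initial Swing", "Midswing",
              "Terminal Swing"),
    lo = c(0, 8, 30, 40, 50, 60, 75, 85),
    hi = c(8, 30, 40, 50, 60, 75, 85, 100)
  )
}

#' Map a continuous gait percent to its classical phase label
#'
#' Converts percent values in `[0, 1)` to the discrete label 0--7 whose
#' percentage interval (half-open `[lo, hi)`) contains `100 * percent`:
#' initial contact `[0, 8)`, mid-stance `[8, 30)`, terminal mid-stance
#' `[30, 40)`, push off `[40, 50)`, pre-swing `[50, 60)`, initial swing
#' `[60, 75)`, midswing `[75, 85)`, terminal swing `[85, 100)`.
#'
#' @param percent Numeric vector in `[0, 1)`.
#' @return Integer vector of phase labels 0--7.
#' @export
#' @examples
#' percent_to_phase(c(0, 0.45, 0.80))   # 0, 3, 6
percent_to_phase <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent >= 1)) {
    stop("`percent` must lie in [0, 1)", call. = FALSE)
  }
  findInterval(100 * percent, c(8, 30, 40, 50, 60, 75, 85))
}
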