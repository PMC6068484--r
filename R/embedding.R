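#' Delay-embedding configuration
#'
#' Parameters of the delayed input window: the full past-window length `d`,
#' the exponential window size `delta` (number of exponents), its base, and
#' the forecast horizon `f`. The exponential window must fit inside the
#' delay window: `round(base^delta) <= d`.
#'
#' @param d Past-window length in samples (>= 1). Default 16, which covers
#'   the largest default exponential offset (10) with margin.
#' @param delta Exponential window size: offsets are `round(base^k)` for
#'   `k = 0..delta`. Default 5.
#' @param base Exponential base (> 1), dimensionless. Default 1.6; use
#'   `exp(1)` for the natural-base variant.
#' @param f Forecast horizon in samples (>= 1). Default 1 (10 ms ahead).
#' @return An object of class `delay_config`.
#' @export
#' @examples
#' delay_config()
delay_config <- function(d = 16, delta = 5, base = 1.6, f = 1) {
  stopifnot(d >= 1, delta >= 0, f >= 1)
  if (base <= 1) stop("`base` must be > 1", call. = FALSE)
  if (round(base^delta) > d) {
    stop("exponential window exceeds the delay window: round(base^delta) = ",
         round(base^delta), " > d = ", d, call. = FALSE)
  }
  structure(list(d = as.integer(d), delta = as.integer(delta),
                 base = base, f = as.integer(f)),
            class = "delay_config")
}

#' @export
print.delay_config <- function(x, ...) {
  cat(sprintf("<delay_config> d = %d, delta = %d, base = %g, f = %d; offsets {%s}\n",
              x$d, x$delta, x$base, x$f,
              paste(exponential_offsets(x$delta, x$base), collapse = ", ")))
  invisible(x)
}

#' Exponentially spaced past offsets
#'
#' The offset set \eqn{\{\mathrm{round}(b^k) : k = 0 \dots \delta\}},
#' sorted and deduplicated. Offset `o` means "sample `t - o`": the set is
#' dense near the present and sparse in the past, trading off short and
#' long delays.
#'
#' @param delta Number of exponents (>= 0).
#' @param base Exponential base (> 1).
#' @return Sorted unique integer vector of past offsets (always contains 1).
#' @export
#' @examples
#' exponential_offsets(5, 1.6)     # 1 2 3 4 7 10
#' exponential_offsets(3, exp(1))  # 1 3 7 20
exponential_offsets <- function(delta, base) {
  stopifnot(delta >= 0)
  if (base <= 1) stop("`base` must be > 1", call. = FALSE)
  sort(unique(as.integer(round(base^(0:delta)))))
}

# Internal: build an embedded dataset from a gait_samples tibble given a
# set of past lags (0 = current sample). Anchors follow the index range
# t = d .. T-1-f (0-based), i.e. rows (d+1) .. (T-f) in 1-based R indexing,
# so the row count is always T - d - f for both window variants.
.embed_with_lags <- function(samples, cfg, lags, variant,
                             keep_boundary = TRUE, targets_ahead = TRUE) {
  stopifnot(inherits(samples, "gait_samples"), inherits(cfg, "delay_config"))
  channels <- attr(samples, "channels")
  Tn <- nrow(samples)
  if (Tn <= cfg$d + cfg$f) {
    stop("insufficient data: need more than d + f = ", cfg$d + cfg$f,
         " samples, got ", Tn, call. = FALSE)
  }
  anchors <- (cfg$d + 1):(Tn - cfg$f)
  Xs <- as.matrix(tibble::as_tibble(samples)[, channels, drop = FALSE])
  cols <- vector("list", length(channels) * length(lags))
  cn <- character(length(cols))
  j <- 0
  for (ch in seq_along(channels)) {
    for (lag in lags) {
      j <- j + 1
      cols[[j]] <- Xs[anchors - lag, ch]
      cn[j] <- sprintf("%s_lag%d", channels[ch], lag)
    }
  }
  Xd <- do.call(cbind, cols)
  colnames(Xd) <- cn
  y <- samples$percent
  off <- if (targets_ahead) seq_len(cfg$f) else seq_len(cfg$f) - 1L
  Yd <- vapply(off, function(k) y[anchors + k], numeric(length(anchors)))
  Yd <- matrix(Yd, ncol = cfg$f)
  cyc <- samples$cycle[anchors]
  keep <- rep(TRUE, length(anchors))
  if (!keep_boundary) {
    keep <- samples$cycle[anchors - max(lags)] == samples$cycle[anchors + cfg$f]
  }
  sensor <- substr(channels, 1, 1)
  feat_sensor <- rep(sensor, each = length(lags))
  branches <- lapply(split(seq_along(cn), factor(feat_sensor, unique(sensor))),
                     as.integer)
  names(branches) <- c(g = "gyro", a = "accel")[names(branches)]
  structure(
    list(X = Xd[keep, , drop = FALSE],
         Y = Yd[keep, , drop = FALSE],
         t_index = samples$t[anchors][keep],
         cycle = cyc[keep],
         cfg = cfg,
         lags = as.integer(lags),
         channels = channels,
         branches = branches,
         variant = variant),
    class = "gait_embedding"
  )
}

#' Build the fully delayed input tensor
#'
#' For each anchor sample `t` in the (0-based) range `d .. T-1-f`, the
#' feature row holds the complete past window of `d + 1` samples per
#' channel (lags `0 .. d`), and the target row holds the next `f` percent
#' labels. The row count is always `T - d - f`.
#'
#' @param samples A `gait_samples` dataset from [build_percent_matrix()].
#' @param cfg A [delay_config()].
#' @inheritParams apply_exponential_window
#' @return A `gait_embedding`: list with feature matrix `X`
#'   (rows x `(d+1) * n_channels`), target matrix `Y` (rows x `f`),
#'   `t_index`, `cycle`, `lags`, `branches`, and `cfg`.
#' @export
build_delayed_tensor <- function(samples, cfg, keep_boundary = TRUE,
                                 targets_ahead = TRUE) {
  .embed_with_lags(samples, cfg, lags = 0:cfg$d, variant = "full",
                   keep_boundary = keep_boundary,
                   targets_ahead = targets_ahead)
}

#' Sub-sample the delay window exponentially
#'
#' Per anchor `t`, the features are the current sample `X[t]` plus
#' `X[t - o]` for every offset `o` in [exponential_offsets()], concatenated
#' per channel, so the feature count is
#' `(n_offsets + 1) * n_channels`. Equivalent to selecting the exponential
#' lag columns from [build_delayed_tensor()].
#'
#' @param samples A `gait_samples` dataset.
#' @param cfg A [delay_config()].
#' @param keep_boundary Keep rows whose window or target spans a gait-cycle
#'   boundary (default `TRUE`; the model must learn the percent reset).
#'   `FALSE` drops them, for ablation.
#' @param targets_ahead If `TRUE` (default) targets are the strictly future
#'   labels `y[t+1] .. y[t+f]`; if `FALSE`, `y[t] .. y[t+f-1]`, for
#'   ablation.
#' @return A `gait_embedding` (see [build_delayed_tensor()]).
#' @export
#' @examples
#' rec <- simulate_recording(subject_profile(), n_cycles = 4, seed = 1)
#' samples <- build_percent_matrix(rec, segment_cycles(rec, detect_heel_strikes(rec)))
#' emb <- apply_exponential_window(samples, delay_config())
#' dim(emb$X)   # rows x 42 features
apply_exponential_window <- function(samples, cfg, keep_boundary = TRUE,
                                     targets_ahead = TRUE) {
  offs <- exponential_offsets(cfg$delta, cfg$base)
  if (max(offs) > cfg$d) {
    stop("exponential window exceeds the delay window", call. = FALSE)
  }
  .embed_with_lags(samples, cfg, lags = c(0L, offs), variant = "exponential",
                   keep_boundary = keep_boundary,
                   targets_ahead = targets_ahead)
}

#' Forecast targets for a set of anchors
#'
#' Row for anchor `t` is `y[t+1], ..., y[t+f]` (the strictly future labels;
#' the network is obliged to predict `f` percentage values in advance).
#'
#' @param y Percent label vector.
#' @param anchors 1-based anchor indices; `anchors + f` must stay in bounds.
#' @param f Forecast horizon (>= 1).
#' @param ahead If `FALSE`, targets start at `t` instead of `t + 1`.
#' @return Matrix with `length(anchors)` rows and `f` columns.
#' @export
#' @examples
#' build_targets(seq(0, 0.9, by = 0.1), anchors = c(2, 5), f = 3)
build_targets <- function(y, anchors, f, ahead = TRUE) {
  stopifnot(f >= 1)
  off <- if (ahead) seq_len(f) else seq_len(f) - 1L
  if (min(anchors) + min(off) < 1 || max(anchors) + max(off) > length(y)) {
    stop("anchor + horizon out of bounds", call. = FALSE)
  }
  out <- vapply(off, function(k) y[anchors + k], numeric(length(anchors)))
  matrix(out, ncol = f)
}

#' @export
print.gait_embedding <- function(x, ...) {
  cat(sprintf("<gait_embedding> %d rows x %d features (%s window), f = %d, %d cycles\n",
              nrow(x$X), ncol(x$X), x$variant, x$cfg$f,
              length(unique(x$cycle))))
  invisible(x)
}

#' Concatenate embedded datasets from several recordings
#'
#' Stacks compatible embeddings (same configuration, channels, and window
#' variant) into one dataset, re-numbering cycles so they stay unique
#' across sources. Used to build the joined multi-subject dataset; windows
#' never span two sources.
#'
#' @param embeddings List of `gait_embedding` objects.
#' @return A single `gait_embedding`.
#' @export
join_embeddings <- function(embeddings) {
  stopifnot(length(embeddings) >= 1,
            all(vapply(embeddings, inherits, logical(1), "gait_embedding")))
  ref <- embeddings[[1]]
  for (e in embeddings[-1]) {
    if (!identical(e$lags, ref$lags) || !identical(e$channels, ref$channels) ||
        !identical(unclass(e$cfg), unclass(ref$cfg))) {
      stop("embeddings are not compatible", call. = FALSE)
    }
  }
  offset <- 0L
  cycles <- lapply(embeddings, function(e) {
    out <- e$cycle + offset
    offset <<- offset + max(e$cycle)
    out
  })
  structure(
    list(X = do.call(rbind, lapply(embeddings, `[[`, "X")),
         Y = do.call(rbind, lapply(embeddings, `[[`, "Y")),
         t_index = unlist(lapply(embeddings, `[[`, "t_index")),
         cycle = unlist(cycles),
         cfg = ref$cfg, lags = ref$lags, channels = ref$channels,
         branches = ref$branches, variant = ref$variant),
    class = "gait_embedding"
  )
}

#' Segment, label, and embed a recording in one step
#'
#' Convenience pipeline: [detect_heel_strikes()] on the heel FSR,
#' [segment_cycles()], [build_percent_matrix()], then
#' [apply_exponential_window()].
#'
#' @param recording A `gait_recording`.
#' @param cfg A [delay_config()].
#' @param channels IMU channels to use (default all six).
#' @param quantize Quantize percent labels to 1% bins. Default `FALSE`.
#' @param ... Passed to [detect_heel_strikes()].
#' @return A `gait_embedding`.
#' @export
#' @examples
#' rec <- simulate_recording(subject_profile(), n_cycles = 5, seed = 1)
#' embed_recording(rec, delay_config())
embed_recording <- function(recording, cfg = delay_config(),
                            channels = c("gx", "gy", "gz", "ax", "ay", "az"),
                            quantize = FALSE, ...) {
  events <- detect_heel_strikes(recording, ...)
  cycles <- segment_cycles(recording, events)
  samples <- build_percent_matrix(recording, cycles, quantize = quantize,
                                  channels = channels)
  apply_exponential_window(samples, cfg)
}
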