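# Shared in-code fixtures: tiny labeled datasets and embeddings built by
# hand so expected values can be enumerated.

# A minimal gait_samples tibble with a percent ramp and random channels.
make_samples <- function(n, n_cycles = 1, channels = c("gx", "gy", "gz",
                                                       "ax", "ay", "az"),
                         seed = 42) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      t = seq_len(n),
      cycle = rep(seq_len(n_cycles), each = ceiling(n / n_cycles))[seq_len(n)]
    )
    out$percent <- unlist(lapply(split(seq_len(n), out$cycle), function(i) {
      (seq_along(i) - 1) / length(i)
    }), use.names = FALSE)
    for (ch in channels) out[[ch]] <- rnorm(n)
    structure(out, channels = channels,
              class = c("gait_samples", class(out)))
  })
}

# A hand-built embedding (for model tests that bypass the windowing stage).
make_embedding <- function(X, Y, cycle = NULL, branches = NULL) {
  if (is.null(cycle)) cycle <- rep(seq_len(10), length.out = nrow(X))
  if (is.null(branches)) {
    half <- ncol(X) %/% 2
    branches <- list(gyro = seq_len(half),
                     accel = seq(half + 1, ncol(X)))
  }
  structure(
    list(X = X, Y = as.matrix(Y), t_index = seq_len(nrow(X)),
         cycle = cycle, cfg = delay_config(), lags = NA_integer_,
         channels = colnames(X), branches = branches,
         variant = "manual"),
    class = "gait_embedding"
  )
}

# Column index of the full delayed tensor holding `channel` at `lag`
# (channel-major layout, lags 0..d).
full_tensor_col <- function(channel_idx, lag, d) {
  (channel_idx - 1) * (d + 1) + lag + 1
}

# Parameters at a generic point for finite-difference gradient checks:
# biases are jittered away from zero so no ReLU pre-activation sits exactly
# on the kink (where the subgradient and the central difference disagree).
make_generic_params <- function(k, hidden, f, seed) {
  params <- init_edfnn(k, hidden = hidden, f = f, seed = seed)
  withr::with_seed(seed + 1000, {
    params$branches <- lapply(params$branches, function(layers) {
      lapply(layers, function(lay) {
        lay$bias <- runif(length(lay$bias), -0.2, 0.2)
        lay
      })
    })
    params$head$bias <- runif(length(params$head$bias), -0.2, 0.2)
  })
  params
}

# Single branched network on a dataset whose target is a noiseless linear
# map of the features: realizable, so training should drive the cost to ~0.
make_linear_dataset <- function(n = 2000, k = 6, seed = 7) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * k, -1, 1), n, k)
    colnames(X) <- paste0("f", seq_len(k))
    y <- 0.5 + 0.3 * X[, 1] - 0.2 * X[, 4] + 0.1 * X[, 6]
    make_embedding(X, y)
  })
}
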