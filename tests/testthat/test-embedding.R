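test_that("exponential offsets round, dedupe, and sort", {
  expect_identical(exponential_offsets(0, 1.6), 1L)
  expect_identical(exponential_offsets(0, 5), 1L)
  expect_identical(exponential_offsets(5, 1.6), c(1L, 2L, 3L, 4L, 7L, 10L))
  expect_identical(exponential_offsets(3, exp(1)), c(1L, 3L, 7L, 20L))
  expect_error(exponential_offsets(3, 1), "> 1")
  # gaps between consecutive offsets never shrink (dense near the present)
  for (delta in 2:8) {
    offs <- exponential_offsets(delta, 1.6)
    expect_true(all(diff(diff(offs)) >= 0))
  }
})

test_that("delay config validates the window geometry", {
  cfg <- delay_config()
  expect_equal(cfg$d, 16L)
  expect_error(delay_config(base = 0.9), "> 1")
  expect_error(delay_config(d = 5, delta = 5, base = 1.6), "exceeds")
})

test_that("full delayed tensor enumerates anchors d .. T-1-f", {
  s <- make_samples(10)
  emb <- build_delayed_tensor(s, delay_config(d = 5, delta = 0, f = 3))
  expect_equal(nrow(emb$X), 2)                 # anchors at 0-based t = 5, 6
  expect_equal(emb$t_index, c(6L, 7L))         # 1-based rows
  expect_equal(ncol(emb$X), 6 * 6)             # (d + 1) samples x 6 channels

  s4 <- make_samples(4)
  emb4 <- build_delayed_tensor(s4, delay_config(d = 1, delta = 0, f = 1))
  expect_equal(emb4$t_index, c(2L, 3L))

  # row count is T - d - f for arbitrary valid configurations
  for (p in list(c(30, 4, 2), c(50, 16, 1), c(25, 7, 5))) {
    ss <- make_samples(p[1])
    cfg <- delay_config(d = p[2], delta = 0, f = p[3])
    expect_equal(nrow(build_delayed_tensor(ss, cfg)$X), p[1] - p[2] - p[3])
    expect_equal(nrow(apply_exponential_window(ss, cfg)$X),
                 p[1] - p[2] - p[3])
  }

  expect_error(build_delayed_tensor(make_samples(5),
                                    delay_config(d = 4, delta = 0, f = 1)),
               "insufficient data")
})

test_that("windowed features reproduce the raw signal at the right lags", {
  s <- make_samples(30)
  cfg <- delay_config(d = 6, delta = 2, f = 1)
  emb <- apply_exponential_window(s, cfg)
  # anchor row r corresponds to sample t = d + r (1-based t_index)
  gy <- s$gy
  for (r in c(1, 5, 10)) {
    t <- emb$t_index[r]
    expect_equal(unname(emb$X[r, "gy_lag0"]), gy[t])
    expect_equal(unname(emb$X[r, "gy_lag3"]), gy[t - 3])
  }
})

test_that("exponential window equals column selection from the full tensor", {
  # oracle equivalence on random instances
  for (seed in 1:5) {
    s <- make_samples(40, n_cycles = 3, seed = seed)
    cfg <- delay_config(d = 12, delta = 4, f = 2)
    full <- build_delayed_tensor(s, cfg)
    expw <- apply_exponential_window(s, cfg)
    lags <- c(0L, exponential_offsets(cfg$delta, cfg$base))
    sel <- unlist(lapply(seq_len(6), function(ch) {
      full_tensor_col(ch, lags, cfg$d)
    }))
    expect_equal(unname(expw$X), unname(full$X[, sel, drop = FALSE]))
    expect_equal(expw$Y, full$Y)
  }
})

test_that("feature count is (n_offsets + 1) x channels", {
  s <- make_samples(60)
  for (delta in c(0, 3, 5)) {
    cfg <- delay_config(d = 16, delta = delta, f = 1)
    emb <- apply_exponential_window(s, cfg)
    m <- length(exponential_offsets(delta, 1.6))
    expect_equal(ncol(emb$X), (m + 1) * 6)
  }
  # delta = 0: each row holds the current sample and lag 1 only
  emb0 <- apply_exponential_window(s, delay_config(d = 16, delta = 0))
  expect_equal(sort(unique(emb0$lags)), c(0L, 1L))
})

test_that("embedding a shifted signal yields shifted rows", {
  s <- make_samples(50, seed = 9)
  cfg <- delay_config(d = 8, delta = 3, f = 1)
  emb1 <- apply_exponential_window(s, cfg)
  shift <- 4
  s2 <- s[(shift + 1):nrow(s), ]
  s2$t <- seq_len(nrow(s2))
  class(s2) <- class(s)
  attr(s2, "channels") <- attr(s, "channels")
  emb2 <- apply_exponential_window(s2, cfg)
  n2 <- nrow(emb2$X)
  expect_equal(unname(emb2$X), unname(emb1$X[(shift + 1):(shift + n2), ]))
})

test_that("targets are the strictly future labels", {
  y <- seq(0, 0.99, by = 0.01)
  # ramp with step 0.01: the f = 1 target is y + 0.01
  tg <- build_targets(y, anchors = 10:20, f = 1)
  expect_equal(drop(tg), y[10:20] + 0.01)

  tg3 <- build_targets(y, anchors = 5, f = 3)
  expect_equal(dim(tg3), c(1, 3))
  expect_equal(drop(tg3), y[6:8])

  # ablation variant starts at t instead of t + 1
  tg0 <- build_targets(y, anchors = 5, f = 2, ahead = FALSE)
  expect_equal(drop(tg0), y[5:6])

  expect_error(build_targets(y, anchors = 100, f = 1), "out of bounds")
})

test_that("targets wrap the sawtooth across a cycle boundary", {
  # two 10-sample cycles: labels reset to 0 at sample 11
  y <- c((0:9) / 10, (0:9) / 10)
  tg <- build_targets(y, anchors = 8:11, f = 3)
  expect_equal(tg[3, ], c(0, 0.1, 0.2))    # anchor 10: next three wrap
  expect_equal(tg[2, ], c(0.9, 0, 0.1))    # anchor 9 spans the reset
})

test_that("boundary-spanning rows can be dropped for ablation", {
  s <- make_samples(60, n_cycles = 3, seed = 2)
  cfg <- delay_config(d = 4, delta = 1, f = 1)
  keep <- apply_exponential_window(s, cfg)
  drop_ <- apply_exponential_window(s, cfg, keep_boundary = FALSE)
  expect_lt(nrow(drop_$X), nrow(keep$X))
  # remaining rows have window and target inside one cycle
  expect_true(all(drop_$Y[, 1] > 0))
})

test_that("joining embeddings stacks rows and renumbers cycles", {
  s1 <- make_samples(40, n_cycles = 2, seed = 1)
  s2 <- make_samples(30, n_cycles = 2, seed = 2)
  cfg <- delay_config(d = 4, delta = 1, f = 1)
  e1 <- apply_exponential_window(s1, cfg)
  e2 <- apply_exponential_window(s2, cfg)
  j <- join_embeddings(list(e1, e2))
  expect_equal(nrow(j$X), nrow(e1$X) + nrow(e2$X))
  expect_equal(length(unique(j$cycle)),
               length(unique(e1$cycle)) + length(unique(e2$cycle)))
})
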