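test_that("relu clamps negatives and passes positives", {
  expect_equal(relu(c(-1, 0, 2.5)), c(0, 0, 2.5))
  expect_equal(relu(matrix(c(-2, 3), 1)), matrix(c(0, 3), 1))
})

test_that("layer forward computes activation(theta a + bias)", {
  # zero weights: output is the clamped bias
  p0 <- list(theta = matrix(0, 3, 2), bias = c(-1, 0, 2))
  expect_equal(layer_forward(c(5, 5), p0), c(0, 0, 2))
  # identity weights on non-negative input
  pI <- list(theta = diag(2), bias = c(0, 0))
  expect_equal(layer_forward(c(1, 2), pI), c(1, 2))
  # hand-computed mixed case
  ph <- list(theta = matrix(c(1, -1), 1, 2), bias = 0.5)
  expect_equal(layer_forward(c(2, 1), ph), 1.5)
  expect_error(layer_forward(c(1, 2, 3), ph), "shape mismatch")
})

test_that("branch concatenation preserves order and widths", {
  expect_equal(concat_branches(list(1:3, 4:5)), 1:5)
  expect_equal(length(concat_branches(list(rnorm(6), rnorm(6)))), 12)
  v <- rnorm(4)
  expect_equal(concat_branches(list(v)), v)
  A <- matrix(1:4, 2); B <- matrix(5:8, 2)
  expect_equal(concat_branches(list(A, B)), cbind(A, B))
})

test_that("branched forward equals a block-diagonal single network", {
  for (seed in 1:4) {
    k1 <- 5; k2 <- 4; h <- c(3, 3)
    params <- init_edfnn(c(k1, k2), hidden = h, f = 2, seed = seed)
    X <- withr::with_seed(100 + seed, matrix(rnorm(8 * (k1 + k2)), 8))
    branches <- list(seq_len(k1), k1 + seq_len(k2))
    out <- forward_edfnn(params, X, branches)

    # oracle: one branch whose layer weights are block-diagonal
    bdiag2 <- function(A, B) {
      M <- matrix(0, nrow(A) + nrow(B), ncol(A) + ncol(B))
      M[seq_len(nrow(A)), seq_len(ncol(A))] <- A
      M[nrow(A) + seq_len(nrow(B)), ncol(A) + seq_len(ncol(B))] <- B
      M
    }
    single <- list(
      branches = list(lapply(seq_along(h), function(l) {
        list(theta = bdiag2(params$branches[[1]][[l]]$theta,
                            params$branches[[2]][[l]]$theta),
             bias = c(params$branches[[1]][[l]]$bias,
                      params$branches[[2]][[l]]$bias))
      })),
      head = params$head
    )
    out_single <- forward_edfnn(single, X, list(seq_len(k1 + k2)))
    expect_equal(out, out_single)
  }
})

test_that("forward pass matches a pencil-and-paper computation", {
  params <- list(
    branches = list(list(list(
      theta = matrix(c(1, 0, -1,
                       0.5, 0.5, 0), 2, 3, byrow = TRUE),
      bias = c(0, -0.1)))),
    head = list(theta = matrix(c(1, 2), 1, 2), bias = 0.05)
  )
  x <- c(0.2, -0.4, 0.1)
  # hidden: relu((0.1, -0.2)) = (0.1, 0); head: 1*0.1 + 2*0 + 0.05
  expect_equal(drop(forward_edfnn(params, x, list(1:3))), 0.15)

  # all-zero parameters give all-zero output
  zero <- list(branches = list(list(list(theta = matrix(0, 2, 3),
                                         bias = c(0, 0)))),
               head = list(theta = matrix(0, 1, 2), bias = 0))
  expect_equal(drop(forward_edfnn(zero, x, list(1:3))), 0)

  # deterministic across calls
  expect_identical(forward_edfnn(params, x, list(1:3)),
                   forward_edfnn(params, x, list(1:3)))

  expect_error(forward_edfnn(params, c(1, 2), list(1:3)), "layout mismatch")
})

test_that("compiled forward agrees with the R reference forward", {
  params <- init_edfnn(c(21, 21), hidden = c(6, 6), f = 1, seed = 5)
  X <- withr::with_seed(5, matrix(rnorm(50 * 42), 50))
  branches <- list(1:21, 22:42)
  expect_equal(gaitphase:::.edfnn_forward_cpp(params, X, branches),
               forward_edfnn(params, X, branches),
               tolerance = 1e-12)
})

test_that("training cost is the half mean squared error", {
  expect_equal(mse_cost(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_cost(0.2, 0), 0.02)
  p <- c(0.3, 0.1, 0.9); y <- c(0.1, 0.2, 0.5)
  expect_equal(mse_cost(2 * p - y, y), 4 * mse_cost(p, y))  # quadratic
  expect_error(mse_cost(matrix(1, 2, 2), matrix(1, 2, 1)), "shape mismatch")
})

test_that("analytic gradients match central finite differences", {
  # random small models; relative error below 1e-5 for every parameter
  for (seed in 1:3) {
    k <- c(3, 4); hidden <- c(4, 3); f <- 2
    params <- make_generic_params(k, hidden = hidden, f = f, seed = seed)
    branches <- list(1:3, 4:7)
    withr::with_seed(seed * 11, {
      X <- matrix(rnorm(12 * 7), 12)
      Y <- matrix(rnorm(12 * f, sd = 0.3), 12)
    })
    g <- edfnn_gradients(params, X, Y, branches)
    cost_at <- function(p) mse_cost(forward_edfnn(p, X, branches), Y)
    eps <- 1e-6
    check_tensor <- function(get, set) {
      th <- get(params)
      gth <- get(g)
      num <- th
      for (i in seq_along(th)) {
        pp <- params; pm <- params
        tp <- th; tp[i] <- tp[i] + eps
        tm <- th; tm[i] <- tm[i] - eps
        pp <- set(pp, tp); pm <- set(pm, tm)
        num[i] <- (cost_at(pp) - cost_at(pm)) / (2 * eps)
      }
      scale <- pmax(abs(num), 1e-4)
      expect_lt(max(abs(num - gth) / scale), 1e-5)
    }
    for (b in 1:2) for (l in 1:2) {
      check_tensor(function(p) p$branches[[b]][[l]]$theta,
                   function(p, v) { p$branches[[b]][[l]]$theta <- v; p })
      check_tensor(function(p) p$branches[[b]][[l]]$bias,
                   function(p, v) { p$branches[[b]][[l]]$bias <- v; p })
    }
    check_tensor(function(p) p$head$theta,
                 function(p, v) { p$head$theta <- v; p })
    check_tensor(function(p) p$head$bias,
                 function(p, v) { p$head$bias <- v; p })
  }
})

test_that("training drives a realizable linear target to near-zero cost", {
  emb <- make_linear_dataset()
  # least-squares oracle confirms the target is exactly realizable
  ls <- lm.fit(cbind(1, emb$X), emb$Y[, 1])
  expect_lt(mean(ls$residuals^2), 1e-20)
  fit <- fit_edfnn(emb, epochs = 300, learning_rate = 5e-3, seed = 1)
  expect_lt(tail(fit$history$train_cost, 1), 1e-3)
})

test_that("training is bitwise reproducible under a fixed seed", {
  emb <- make_linear_dataset(n = 400)
  f1 <- fit_edfnn(emb, epochs = 20, seed = 3)
  f2 <- fit_edfnn(emb, epochs = 20, seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  f3 <- fit_edfnn(emb, epochs = 20, seed = 4)
  expect_false(identical(f3$history$train_cost, f1$history$train_cost))
})

test_that("learning curve is non-increasing after 10-epoch smoothing", {
  emb <- make_linear_dataset(n = 1000)
  fit <- fit_edfnn(emb, epochs = 120, learning_rate = 1e-3, seed = 2)
  sm <- stats::filter(fit$history$train_cost, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-5))
})

test_that("divergent training fails loudly with the epoch", {
  emb <- make_linear_dataset(n = 300)
  expect_error(
    fit_edfnn(emb, epochs = 30, learning_rate = 1e9, optimizer = "sgd",
              seed = 1),
    "training failure.*epoch"
  )
})

test_that("forecasts are clamped into [0, 1) and track the next label", {
  expect_equal(clamp_percent(1.3), 1 - 1e-9)
  expect_equal(clamp_percent(-0.2), 0)

  rec <- simulate_recording(subject_profile(), n_cycles = 40, seed = 6)
  emb <- embed_recording(rec)
  parts <- split_by_cycles(emb, seed = 6)
  fit <- fit_edfnn(parts$train, epochs = 80, seed = 6)
  fc <- forecast_percent(fit, parts$validation$X)
  expect_true(all(fc >= 0 & fc < 1))
  # forecast at anchor t approximates the generator's next label
  expect_lt(mean(abs(fc - parts$validation$Y)), 0.05)
})

test_that("run-to-run variance of final validation MSE stays below its mean", {
  rec <- simulate_recording(subject_profile(), n_cycles = 60, seed = 8)
  emb <- embed_recording(rec)
  exper <- run_experiment(emb, n_runs = 10, epochs = 60)
  expect_true(all(is.na(exper$error)))
  expect_lt(sd(exper$v_mse), mean(exper$v_mse))
})

test_that("tidy and glance summarise a fitted network", {
  emb <- make_linear_dataset(n = 300)
  fit <- fit_edfnn(emb, epochs = 10, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("component", "layer", "n_params") %in% names(td)))
  expect_equal(sum(td$component == "head"), 1)
  gl <- glance(fit)
  expect_equal(gl$epochs, 10L)
  expect_equal(gl$n_branches, 2L)
})
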