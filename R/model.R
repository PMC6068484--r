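#' Rectified linear activation
#'
#' Elementwise `max(0, z)`, used on all hidden layers to avoid gradient
#' saturation.
#'
#' @param z Numeric vector or matrix.
#' @return Same shape as `z`.
#' @export
#' @examples
#' relu(c(-1, 0, 2.5))
relu <- function(z) {
  pmax(z, 0)
}

#' Forward pass through one fully connected layer
#'
#' Computes `activation(theta %*% a_prev + bias)`. `a_prev` may be a vector
#' (one sample) or a matrix with one sample per row.
#'
#' @param a_prev Numeric vector of length `k`, or an `n x k` matrix.
#' @param params List with `theta` (`n_units x k` weight matrix) and `bias`
#'   (length `n_units`).
#' @param activation Activation function. Default [relu()]; use `identity`
#'   for a linear layer.
#' @return Activation vector (or `n x n_units` matrix).
#' @export
#' @examples
#' layer_forward(c(2, 1), list(theta = matrix(c(1, -1), 1), bias = 0.5))
layer_forward <- function(a_prev, params, activation = relu) {
  theta <- params$theta
  bias <- params$bias
  vec_in <- is.null(dim(a_prev))
  A <- if (vec_in) matrix(a_prev, nrow = 1) else as.matrix(a_prev)
  if (ncol(A) != ncol(theta)) {
    stop("shape mismatch: layer expects ", ncol(theta), " inputs, got ",
         ncol(A), call. = FALSE)
  }
  out <- activation(A %*% t(theta) + matrix(bias, nrow(A), length(bias),
                                            byrow = TRUE))
  if (vec_in) drop(out) else out
}

#' Concatenate per-sensor branch outputs
#'
#' Joins the output activations of the per-sensor branches into a single
#' feature vector (or matrix, samples in rows), preserving branch order,
#' before the shared output head.
#'
#' @param branch_outputs List of numeric vectors, or of matrices with equal
#'   row counts.
#' @return A single vector or matrix.
#' @export
#' @examples
#' concat_branches(list(1:3, 4:5))
concat_branches <- function(branch_outputs) {
  stopifnot(length(branch_outputs) >= 1)
  if (is.null(dim(branch_outputs[[1]]))) {
    unlist(branch_outputs, use.names = FALSE)
  } else {
    do.call(cbind, branch_outputs)
  }
}

#' Initialise branched-network parameters
#'
#' Scaled uniform initialisation keyed to fan-in: each weight is drawn from
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`; biases start at zero. Seeded and
#' fully reproducible.
#'
#' @param branch_inputs Integer vector: number of input features per branch.
#' @param hidden Hidden-layer widths per branch. Default `c(6, 6)`.
#' @param f Output width (forecast horizon). Default 1.
#' @param seed Integer seed.
#' @return Parameter list with elements `branches` (per branch, a list of
#'   `list(theta, bias)` layers) and `head`.
#' @export
init_edfnn <- function(branch_inputs, hidden = c(6, 6), f = 1, seed = 1) {
  stopifnot(length(branch_inputs) >= 1, all(branch_inputs >= 1),
            all(hidden >= 1), f >= 1)
  withr::with_seed(seed, {
    make_layer <- function(n_in, n_out) {
      s <- 1 / sqrt(n_in)
      list(theta = matrix(runif(n_out * n_in, -s, s), n_out, n_in),
           bias = rep(0, n_out))
    }
    branches <- lapply(branch_inputs, function(k) {
      widths <- c(k, hidden)
      lapply(seq_along(hidden), function(l) make_layer(widths[l], widths[l + 1]))
    })
    head <- make_layer(length(branch_inputs) * hidden[length(hidden)], f)
    list(branches = branches, head = head)
  })
}

#' Forward pass through the branched network (reference implementation)
#'
#' Plain-R forward pass: each sensor's feature block flows through its own
#' stack of ReLU hidden layers, the branch outputs are concatenated, and a
#' linear head maps them to the `f` forecast outputs. Numerically identical
#' to the compiled training-path forward and used as its cross-check.
#'
#' @param params Parameter list from [init_edfnn()] (or a fitted model's
#'   `$params`).
#' @param X Feature matrix (rows = samples) or a single feature vector.
#' @param branches List of feature-column indices, one per branch.
#' @return `n x f` matrix of raw (unclamped) percent estimates.
#' @export
forward_edfnn <- function(params, X, branches) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (max(unlist(branches)) > ncol(X)) {
    stop("layout mismatch: branch columns exceed feature count", call. = FALSE)
  }
  outs <- purrr::map2(params$branches, branches, function(layers, cols) {
    A <- X[, cols, drop = FALSE]
    for (lay in layers) A <- layer_forward(A, lay, activation = relu)
    A
  })
  C <- concat_branches(outs)
  layer_forward(C, params$head, activation = identity)
}

#' Half mean-squared-error training cost
#'
#' The training objective
#' \eqn{\frac{1}{2N}\sum_i \lVert \hat y_i - y_i\rVert^2}. The 1/2 factor
#' simplifies the gradient and is used for training only; reported metrics
#' use the standard MSE of [mse_metric()].
#'
#' @param pred,truth Matrices (or vectors) of equal shape, `N >= 1` rows.
#' @return Scalar cost.
#' @export
#' @examples
#' mse_cost(0.2, 0)   # 0.02
mse_cost <- function(pred, truth) {
  pred <- as.matrix(pred)
  truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) {
    stop("shape mismatch between `pred` and `truth`", call. = FALSE)
  }
  sum((pred - truth)^2) / (2 * nrow(pred))
}

#' Fit the branched gait-percent network
#'
#' Trains the per-sensor branched feed-forward network on an embedded
#' dataset by minibatch backpropagation of the half-MSE cost
#' ([mse_cost()]). Features are standardised per column using the training
#' data's statistics (stored with the model and applied at prediction
#' time). Fully reproducible: the same seed gives bitwise-identical
#' parameters and learning curves.
#'
#' @param embedding Training `gait_embedding` from
#'   [apply_exponential_window()] or [build_delayed_tensor()].
#' @param validation Optional `gait_embedding` scored after every epoch.
#' @param hidden Hidden-layer widths per branch. Default `c(6, 6)`.
#' @param learning_rate Optimizer step size. Default `1e-3`.
#' @param epochs Training epochs (>= 1). Default 200.
#' @param batch_size Minibatch size. Default 256.
#' @param optimizer `"adam"` (default) or `"sgd"` (plain gradient descent).
#' @param seed Integer seed for initialisation and batch shuffling.
#' @return An object of class `edfnn`: parameters, feature normalisation
#'   statistics, branch layout, the [delay_config()], and a `history`
#'   tibble with per-epoch train (and validation) cost.
#' @export
#' @examples
#' rec <- simulate_recording(subject_profile(), n_cycles = 10, seed = 1)
#' emb <- embed_recording(rec)
#' fit <- fit_edfnn(emb, epochs = 5)
#' glance(fit)
fit_edfnn <- function(embedding, validation = NULL, hidden = c(6, 6),
                      learning_rate = 1e-3, epochs = 200, batch_size = 256,
                      optimizer = c("adam", "sgd"), seed = 1) {
  stopifnot(inherits(embedding, "gait_embedding"), nrow(embedding$X) >= 1,
            learning_rate > 0, epochs >= 1, batch_size >= 1)
  optimizer <- match.arg(optimizer)
  X <- embedding$X
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  branches <- embedding$branches
  f <- ncol(embedding$Y)

  params <- init_edfnn(vapply(branches, length, integer(1)),
                       hidden = hidden, f = f, seed = seed)
  shuffle_seed <- withr::with_seed(seed, sample.int(.Machine$integer.max, 1))

  Xv <- Yv <- NULL
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "gait_embedding"))
    Xv <- sweep(sweep(validation$X, 2, mu), 2, sigma, "/")
    Yv <- validation$Y
  }
  res <- .edfnn_train_cpp(params, Xs, embedding$Y, Xv, Yv,
                          unname(branches), learning_rate,
                          as.integer(epochs), as.integer(batch_size),
                          optimizer, shuffle_seed)
  if (res$diverged > 0) {
    stop("training failure: cost became non-finite at epoch ", res$diverged,
         call. = FALSE)
  }
  history <- tibble::tibble(epoch = seq_len(epochs),
                            train_cost = res$train_cost,
                            val_cost = res$val_cost)
  structure(
    list(params = list(branches = res$branches, head = res$head),
         branches = branches,
         channels = embedding$channels,
         lags = embedding$lags,
         cfg = embedding$cfg,
         norm = list(mu = mu, sigma = sigma),
         hidden = hidden,
         optimizer = optimizer,
         learning_rate = learning_rate,
         epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         seed = seed,
         history = history),
    class = "edfnn"
  )
}

#' @export
print.edfnn <- function(x, ...) {
  cat(sprintf(
    "<edfnn> %d branch(es) x hidden [%s], f = %d, %s lr %g, %d epochs\n",
    length(x$branches), paste(x$hidden, collapse = ", "),
    ncol(x$params$head$theta) * 0 + length(x$params$head$bias),
    x$optimizer, x$learning_rate, x$epochs))
  cat(sprintf("  final train cost %.3g", utils::tail(x$history$train_cost, 1)))
  if (!all(is.na(x$history$val_cost))) {
    cat(sprintf(", val cost %.3g", utils::tail(x$history$val_cost, 1)))
  }
  cat("\n")
  invisible(x)
}

#' Predict gait percent for embedded samples
#'
#' @param object A fitted `edfnn`.
#' @param newdata A `gait_embedding` or a feature matrix/vector with the
#'   model's feature layout.
#' @param clamp Clamp outputs into `[0, 1)`. Default `FALSE` (raw
#'   regression outputs).
#' @param ... Unused.
#' @return `n x f` matrix of percent estimates.
#' @export
predict.edfnn <- function(object, newdata, clamp = FALSE, ...) {
  X <- if (inherits(newdata, "gait_embedding")) newdata$X else newdata
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(object$norm$mu)) {
    stop("layout mismatch: model expects ", length(object$norm$mu),
         " features", call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, object$norm$mu), 2, object$norm$sigma, "/")
  out <- forward_edfnn(object$params, Xs, object$branches)
  if (clamp) out <- clamp_percent(out)
  out
}

#' Forecast future gait percent from the most recent window
#'
#' Alias of [predict.edfnn()] with outputs clamped to `[0, 1)`. The first
#' output corresponds to `t + 1`, i.e. 10 ms ahead of the newest sample in
#' the window, so an actuation decision needs no detection delay.
#'
#' @param model A fitted `edfnn`.
#' @param recent_window Feature vector (or matrix) in the model's layout.
#' @return Matrix of `f` future percent values per row, each in `[0, 1)`.
#' @export
forecast_percent <- function(model, recent_window) {
  predict(model, recent_window, clamp = TRUE)
}

#' Clamp raw percent estimates into `[0, 1)`
#'
#' @param x Numeric vector or matrix.
#' @return `x` clamped to `[0, 1 - 1e-9]`.
#' @export
clamp_percent <- function(x) {
  pmin(pmax(x, 0), 1 - 1e-9)
}

#' Analytic gradients of the training cost
#'
#' Backpropagated gradients of [mse_cost()] with respect to every weight
#' and bias, computed by the compiled training core. Used by the
#' finite-difference gradient check.
#'
#' @param params Parameter list ([init_edfnn()] layout).
#' @param X Feature matrix, `Y` target matrix.
#' @param Y Target matrix (`n x f`).
#' @param branches List of feature-column indices per branch.
#' @return List with the same structure as `params` plus `cost`.
#' @export
edfnn_gradients <- function(params, X, Y, branches) {
  .edfnn_grad_cpp(params, as.matrix(X), as.matrix(Y), unname(branches))
}

#' @export
tidy.edfnn <- function(x, ...) {
  rows <- list()
  for (b in seq_along(x$params$branches)) {
    layers <- x$params$branches[[b]]
    for (l in seq_along(layers)) {
      th <- layers[[l]]$theta
      rows[[length(rows) + 1]] <- tibble::tibble(
        component = names(x$branches)[b], layer = l,
        n_in = ncol(th), n_out = nrow(th),
        n_params = length(th) + nrow(th),
        mean_abs_weight = mean(abs(th)))
    }
  }
  th <- x$params$head$theta
  rows[[length(rows) + 1]] <- tibble::tibble(
    component = "head", layer = 1L, n_in = ncol(th), n_out = nrow(th),
    n_params = length(th) + nrow(th), mean_abs_weight = mean(abs(th)))
  dplyr::bind_rows(rows)
}

#' @export
glance.edfnn <- function(x, ...) {
  tibble::tibble(
    n_branches = length(x$branches),
    n_features = length(x$norm$mu),
    f = length(x$params$head$bias),
    epochs = x$epochs,
    optimizer = x$optimizer,
    final_train_cost = utils::tail(x$history$train_cost, 1),
    final_val_cost = utils::tail(x$history$val_cost, 1)
  )
}
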