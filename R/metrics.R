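#' Mean squared error (reporting form)
#'
#' Standard MSE \eqn{\frac{1}{n}\sum_i (\hat y_i - y_i)^2}, without the 1/2
#' factor of the training cost, so reported magnitudes are directly
#' comparable between implementations. Matrices are compared elementwise.
#'
#' @param pred,truth Numeric vectors or matrices of equal shape, `n >= 1`.
#' @return Scalar MSE, on the normalized `[0, 1)` percent scale.
#' @export
#' @examples
#' mse_metric(c(0.1, -0.1), c(0, 0))   # 0.01
mse_metric <- function(pred, truth) {
  pred <- as.numeric(pred)
  truth <- as.numeric(truth)
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  stopifnot(length(pred) >= 1)
  mean((pred - truth)^2)
}

#' Mean absolute error
#'
#' \eqn{\frac{1}{n}\sum_i |\hat y_i - y_i|}.
#'
#' @inheritParams mse_metric
#' @return Scalar MAE on the normalized percent scale.
#' @export
#' @examples
#' mae_metric(c(0.1, 0.3), c(0.2, 0.2))   # 0.1
mae_metric <- function(pred, truth) {
  pred <- as.numeric(pred)
  truth <- as.numeric(truth)
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  stopifnot(length(pred) >= 1)
  mean(abs(pred - truth))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with
#' \eqn{SS_{tot} = \sum_i (\bar y - y_i)^2} and
#' \eqn{SS_{res} = \sum_i (\hat y_i - y_i)^2}. A value of 1 means the
#' prediction fully represents the ground truth; predicting the mean
#' everywhere gives 0.
#'
#' @inheritParams mse_metric
#' @return Scalar R-squared (<= 1; can be negative).
#' @export
#' @examples
#' r_squared(c(0.1, 0.5, 0.9), c(0, 0.5, 1))   # 0.96
r_squared <- function(pred, truth) {
  pred <- as.numeric(pred)
  truth <- as.numeric(truth)
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  stopifnot(length(truth) >= 2)
  ss_tot <- sum((mean(truth) - truth)^2)
  if (ss_tot == 0) {
    stop("R-squared undefined: `truth` is constant", call. = FALSE)
  }
  1 - sum((pred - truth)^2) / ss_tot
}

#' Convert a normalized metric to percent-of-gait-cycle units
#'
#' `MSE% = MSE * 100`, `MAE% = MAE * 100`.
#'
#' @param value Non-negative metric on the normalized scale.
#' @return `value * 100`.
#' @export
#' @examples
#' to_percent(0.021)   # 2.1
to_percent <- function(value) {
  stopifnot(all(value >= 0))
  value * 100
}
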