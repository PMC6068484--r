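#' Plot a gait recording
#'
#' IMU channels and FSR contact pulses over time, faceted per channel.
#'
#' @param object A `gait_recording`.
#' @param max_seconds Plot at most this many seconds. Default 5.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_recording <- function(object, max_seconds = 5, ...) {
  n <- min(nrow(object), max_seconds * 100)
  df <- tibble::as_tibble(object)[seq_len(n), ] |>
    tidyr::pivot_longer(-"t", names_to = "channel", values_to = "value") |>
    dplyr::mutate(seconds = (.data$t - 1) / 100)
  ggplot2::ggplot(df, ggplot2::aes(.data$seconds, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Synthetic walking recording")
}

#' Plot the gait-percent sawtooth of a labeled dataset
#'
#' The ground-truth percent label against time: strictly increasing within
#' each cycle and resetting to zero at every heel strike.
#'
#' @param object A `gait_samples` dataset.
#' @param max_seconds Plot at most this many seconds. Default 5.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_samples <- function(object, max_seconds = 5, ...) {
  df <- tibble::as_tibble(object)
  df <- df[seq_len(min(nrow(df), max_seconds * 100)), ]
  ggplot2::ggplot(df, ggplot2::aes((.data$t - 1) / 100, .data$percent,
                                   group = .data$cycle)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "gait percent (0-1)",
                  title = "Percent labels per gait cycle")
}

#' Plot the learning curve of a fitted network
#'
#' Per-epoch training (and validation) half-MSE cost.
#'
#' @param object A fitted `edfnn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edfnn <- function(object, ...) {
  df <- object$history |>
    tidyr::pivot_longer(-"epoch", names_to = "split", values_to = "cost") |>
    dplyr::filter(is.finite(.data$cost))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$cost,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "cost (half-MSE)",
                  title = "Learning curve")
}

#' Plot the per-run metric distributions of an experiment
#'
#' Validation and training MSE distributions over repeated runs, one
#' violin-style panel of points per dataset.
#'
#' @param object A `gait_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_experiment <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(is.na(.data$error)) |>
    tidyr::pivot_longer(c("t_mse", "v_mse"), names_to = "split",
                        values_to = "mse") |>
    dplyr::mutate(split = dplyr::recode(.data$split, t_mse = "train",
                                        v_mse = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(.data$dataset, .data$mse,
                                   colour = .data$split)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 3, size = 3) +
    ggplot2::labs(x = NULL, y = "MSE (normalized percent scale)",
                  title = "Repeated-run MSE per dataset")
}
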