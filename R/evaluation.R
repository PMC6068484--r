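#' Split an embedded dataset by whole gait cycles
#'
#' Randomly assigns whole cycles (never individual samples) to the training
#' or validation part with a seeded shuffle, so the two parts share no
#' cycle.
#'
#' @param embedding A `gait_embedding`.
#' @param fraction Training fraction, strictly between 0 and 1. Default 0.8.
#' @param seed Integer seed; the same seed reproduces the split.
#' @return Named list with `train` and `validation` embeddings (both
#'   non-empty).
#' @export
#' @examples
#' rec <- simulate_recording(subject_profile(), n_cycles = 10, seed = 1)
#' parts <- split_by_cycles(embed_recording(rec), seed = 1)
#' length(unique(parts$train$cycle))
split_by_cycles <- function(embedding, fraction = 0.8, seed = 1) {
  stopifnot(inherits(embedding, "gait_embedding"),
            fraction > 0, fraction < 1)
  cycles <- unique(embedding$cycle)
  if (length(cycles) < 2) {
    stop("split error: need at least 2 cycles", call. = FALSE)
  }
  n_train <- floor(fraction * length(cycles))
  n_train <- min(max(n_train, 1L), length(cycles) - 1L)
  shuffled <- withr::with_seed(seed, sample(cycles))
  train_cycles <- shuffled[seq_len(n_train)]
  take <- function(rows) {
    out <- embedding
    out$X <- embedding$X[rows, , drop = FALSE]
    out$Y <- embedding$Y[rows, , drop = FALSE]
    out$t_index <- embedding$t_index[rows]
    out$cycle <- embedding$cycle[rows]
    out
  }
  in_train <- embedding$cycle %in% train_cycles
  list(train = take(in_train), validation = take(!in_train))
}

#' Score a fitted model on train and validation splits
#'
#' Computes the six-column metric row (train/validation MSE, MAE,
#' R-squared) on the normalized percent scale. Predictions are clamped to
#' `[0, 1)` before scoring by default.
#'
#' @param fit A fitted `edfnn`.
#' @param train,validation `gait_embedding` splits.
#' @param clamp Clamp predictions before scoring. Default `TRUE`.
#' @return One-row tibble with columns `t_mse, v_mse, t_mae, v_mae, t_r2,
#'   v_r2`.
#' @export
evaluate_edfnn <- function(fit, train, validation, clamp = TRUE) {
  pt <- predict(fit, train, clamp = clamp)
  pv <- predict(fit, validation, clamp = clamp)
  tibble::tibble(
    t_mse = mse_metric(pt, train$Y),
    v_mse = mse_metric(pv, validation$Y),
    t_mae = mae_metric(pt, train$Y),
    v_mae = mae_metric(pv, validation$Y),
    t_r2 = r_squared(pt, train$Y),
    v_r2 = r_squared(pv, validation$Y)
  )
}

#' Repeated-run training and evaluation protocol
#'
#' For every dataset, trains `n_runs` seeded models (fresh cycle-level
#' split, initialisation, and batch shuffling per run) and reports the
#' per-run metric rows -- the numeric content of a violin plot over runs.
#' A per-run training failure is recorded in the `error` column, not fatal
#' to the sweep.
#'
#' @param datasets A named list of `gait_embedding` objects (e.g. one per
#'   subject plus the joined dataset), or a single embedding.
#' @param n_runs Number of repeated runs per dataset. Default 10 (a fast
#'   protocol; 100 reproduces a full violin).
#' @param seeds Integer vector of run seeds (length `n_runs`). Default
#'   `1:n_runs`.
#' @param fraction Training fraction for the cycle-level split. Default 0.8.
#' @param clamp Clamp predictions before scoring. Default `TRUE`.
#' @param ... Passed to [fit_edfnn()] (`hidden`, `epochs`,
#'   `learning_rate`, `batch_size`, `optimizer`).
#' @return A tibble of class `gait_experiment`: one row per dataset x run
#'   with the six metrics, the seed, and `error` (`NA` when the run
#'   succeeded).
#' @export
#' @examples
#' rec <- simulate_recording(subject_profile(), n_cycles = 12, seed = 1)
#' run_experiment(embed_recording(rec), n_runs = 2, epochs = 5)
run_experiment <- function(datasets, n_runs = 10, seeds = NULL,
                           fraction = 0.8, clamp = TRUE, ...) {
  if (inherits(datasets, "gait_embedding")) {
    datasets <- list(dataset = datasets)
  }
  stopifnot(n_runs >= 1,
            all(vapply(datasets, inherits, logical(1), "gait_embedding")))
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  grid <- tidyr::expand_grid(dataset = names(datasets), run = seq_len(n_runs))
  rows <- purrr::pmap(grid, function(dataset, run) {
    seed <- seeds[run]
    base <- tibble::tibble(dataset = dataset, run = run, seed = seed)
    res <- tryCatch({
      parts <- split_by_cycles(datasets[[dataset]], fraction = fraction,
                               seed = seed)
      fit <- fit_edfnn(parts$train, validation = parts$validation,
                       seed = seed, ...)
      dplyr::bind_cols(base,
                       evaluate_edfnn(fit, parts$train, parts$validation,
                                      clamp = clamp),
                       tibble::tibble(error = NA_character_))
    }, error = function(e) {
      dplyr::bind_cols(base, tibble::tibble(
        t_mse = NA_real_, v_mse = NA_real_, t_mae = NA_real_,
        v_mae = NA_real_, t_r2 = NA_real_, v_r2 = NA_real_,
        error = conditionMessage(e)))
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("gait_experiment", class(out)))
}

#' Summarise a repeated-run experiment
#'
#' Mean and standard deviation of every metric per dataset, mirroring a
#' result table with `t-MSE, v-MSE, t-MAE, v-MAE, t-R2, v-R2` columns.
#'
#' @param x A `gait_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble with one row per dataset and `<metric>_mean` /
#'   `<metric>_sd` columns, plus the number of successful runs.
#' @export
tidy.gait_experiment <- function(x, ...) {
  metrics <- c("t_mse", "v_mse", "t_mae", "v_mae", "t_r2", "v_r2")
  tibble::as_tibble(x) |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      dplyr::across(dplyr::all_of(metrics),
                    list(mean = mean, sd = sd)),
      .groups = "drop"
    )
}

#' @export
glance.gait_experiment <- function(x, ...) {
  ok <- tibble::as_tibble(x) |> dplyr::filter(is.na(.data$error))
  tibble::tibble(
    n_datasets = length(unique(x$dataset)),
    n_runs = nrow(x),
    n_failed = sum(!is.na(x$error)),
    v_mse_mean = mean(ok$v_mse),
    v_mae_pct_mean = to_percent(mean(ok$v_mae)),
    v_r2_mean = mean(ok$v_r2)
  )
}

#' Write experiment results as CSV files
#'
#' Emits one CSV with a row per run and a summary CSV with per-dataset
#' mean and standard deviation of each metric.
#'
#' @param x A `gait_experiment`.
#' @param runs_path,summary_path Output CSV paths.
#' @return `runs_path`, invisibly.
#' @export
write_experiment_csv <- function(x, runs_path, summary_path) {
  utils::write.csv(tibble::as_tibble(x), runs_path, row.names = FALSE)
  utils::write.csv(tidy(x), summary_path, row.names = FALSE)
  invisible(runs_path)
}
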