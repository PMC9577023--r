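# Run and comparison exports (CSV metric trajectories, JSON summaries) and
# YAML experiment-config files.

#' Write per-epoch metrics of a run to CSV
#'
#' Columns: epoch, condition, train_loss, test_loss, accuracy, gap.
#'
#' @param run An `fbm_run`.
#' @param file Output path.
#' @export
write_run_csv <- function(run, file) {
  stopifnot(inherits(run, "fbm_run"))
  df <- cbind(epoch = run$metrics$epoch, condition = run$condition,
              run$metrics[, c("train_loss", "test_loss", "accuracy",
                              "gap")])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

config_summary <- function(config) {
  keep <- c("task", "layer_sizes", "loss", "lr", "epochs",
            "batches_per_epoch", "batch_size", "mode", "target_rate",
            "n_fibers", "window_len", "shift", "hurst", "sigma", "dt",
            "rescale", "seed")
  out <- unclass(config)[keep]
  out[!vapply(out, is.null, logical(1))]
}

#' Write a JSON summary of a run
#'
#' Records the condition, configuration snapshot, seed, and final-epoch
#' metrics.
#'
#' @param run An `fbm_run`.
#' @param file Output path.
#' @export
write_run_json <- function(run, file) {
  stopifnot(inherits(run, "fbm_run"))
  fin <- run$metrics[nrow(run$metrics), ]
  obj <- list(
    task = run$task, condition = run$condition,
    config = config_summary(run$config),
    final = list(epoch = fin$epoch, train_loss = fin$train_loss,
                 test_loss = fin$test_loss,
                 accuracy = if (is.na(fin$accuracy)) NULL else fin$accuracy,
                 generalization_gap = fin$gap))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Write a condition comparison to CSV and JSON
#'
#' Writes `trajectories.csv` (per-epoch mean/sd per condition),
#' `final.csv` (final-epoch metrics per seed), and `summary.json`
#' (median final gaps and the shared configuration) under `dir`.
#'
#' @param comparison An `fbm_comparison`.
#' @param dir Output directory (created if needed).
#' @export
write_comparison <- function(comparison, dir) {
  stopifnot(inherits(comparison, "fbm_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(comparison$trajectories,
                   file.path(dir, "trajectories.csv"), row.names = FALSE)
  utils::write.csv(comparison$final, file.path(dir, "final.csv"),
                   row.names = FALSE)
  med <- stats::aggregate(gap ~ condition, data = comparison$final,
                          FUN = stats::median)
  obj <- list(
    n_seeds = comparison$n_seeds,
    median_final_gap = stats::setNames(as.list(med$gap), med$condition),
    config = config_summary(comparison$config))
  jsonlite::write_json(obj, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment configuration from a YAML file
#'
#' The file holds key-value pairs matching [experiment_config()] arguments
#' (e.g. `task`, `layer_sizes`, `mode`, `n_fibers`, `seed`).
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_field("path", paste("unknown config keys:",
                             paste(unknown, collapse = ", ")))
  do.call(experiment_config, vals)
}
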