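# Run configuration and the programmatic surface behind the command-line
# wrapper (inst/cli/emgdyn.R): simulate a dataset to disk, run the factorial
# experiment from a dataset directory, and render summary tables from a
# results directory.

#' Default run configuration
#'
#' A single nested list governing a full run: protocol, window spec,
#' feature, classifier and experiment settings. YAML-serializable; use
#' [read_run_config()] to load a partial YAML overriding these defaults.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    protocol = list(n_classes = 9, n_channels = 6, fs = 1024,
                    reps_per_session = 2, n_sessions = 3,
                    ramp_s = 3, hold_s = 4, rest_s = 3,
                    band_hz = c(47, 440), envelope = "cosine",
                    snr_db_range = c(10, 25), activity_range = c(0.56, 0.92)),
    window = list(length_samples = 128, step_samples = 32),
    experiment = list(n_subjects = 8, vote_depth = 6, train_stride = 4,
                      zc_eps = "adaptive",
                      feature_sets = c("td_ar", "wt"),
                      classifiers = c("lda", "svm_ovo", "svm_ovr"),
                      sections = training_sections()),
    master_seed = 101
  )
}

#' @rdname default_run_config
#' @param path Path to a YAML file; entries override the defaults.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  rlang::check_installed("yaml")
  user <- yaml::read_yaml(path)
  modify_list_deep(cfg, user)
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

config_protocol <- function(cfg) {
  do.call(emg_protocol, cfg$protocol)
}

config_wspec <- function(cfg) {
  window_spec(cfg$window$length_samples, cfg$window$step_samples,
              fs = cfg$protocol$fs)
}

#' Simulate a dataset to disk
#'
#' Generates the configured synthetic dataset and writes it as EDF +
#' annotation CSV pairs (see [write_dataset()]), along with a snapshot of
#' the configuration.
#'
#' @param out_dir Output directory.
#' @param config Configuration list (see [default_run_config()]) or a YAML
#'   path.
#' @param seed Optional master-seed override.
#' @return The output directory, invisibly.
#' @export
cli_simulate <- function(out_dir, config = NULL, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else
    config %||% default_run_config()
  if (!is.null(seed)) cfg$master_seed <- seed
  dataset <- generate_dataset(config_protocol(cfg),
                              n_subjects = cfg$experiment$n_subjects,
                              master_seed = cfg$master_seed)
  write_dataset(dataset, out_dir)
  rlang::check_installed("yaml")
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Run the experiment over a dataset directory
#'
#' Reads a dataset written by [cli_simulate()] (or real recordings in the
#' same layout), runs the configured factorial experiment, and writes
#' `results.csv` (one row per subject x fold x cell).
#'
#' @param data_dir Dataset directory.
#' @param out_dir Results directory.
#' @param config Configuration list or YAML path; defaults to the snapshot
#'   stored in `data_dir` if present.
#' @param only Optional cell restriction, a character vector
#'   `c(feature_set, classifier, section)`.
#' @return The results tibble, invisibly.
#' @export
cli_run <- function(data_dir, out_dir, config = NULL, only = NULL) {
  snap <- file.path(data_dir, "config.yaml")
  cfg <- if (is.character(config)) {
    read_run_config(config)
  } else if (!is.null(config)) {
    config
  } else if (file.exists(snap)) {
    read_run_config(snap)
  } else {
    default_run_config()
  }
  dataset <- read_dataset(data_dir)
  cells <- if (!is.null(only)) {
    stopifnot(length(only) == 3)
    study_cells(only[1], only[2], only[3])
  } else {
    study_cells(cfg$experiment$feature_sets, cfg$experiment$classifiers,
                cfg$experiment$sections)
  }
  results <- run_experiment(
    dataset, cells = cells, wspec = config_wspec(cfg),
    vote_depth = cfg$experiment$vote_depth,
    train_stride = cfg$experiment$train_stride,
    zc_eps = cfg$experiment$zc_eps, seed = cfg$master_seed
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as_tibble(results), file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  invisible(results)
}

#' Render summary tables from a results directory
#'
#' Reads `results.csv` and writes the mean +/- SD summary table and, when
#' the factorial is complete for a cell, the normalized-error table. An
#' incomplete factorial produces a partial table with a warning.
#'
#' @param results_dir Directory containing `results.csv`.
#' @param out_dir Output directory (default `results_dir`).
#' @return List with `summary` and `normalized` tibbles, invisibly.
#' @export
cli_report <- function(results_dir, out_dir = results_dir) {
  path <- file.path(results_dir, "results.csv")
  if (!file.exists(path)) abort(sprintf("no results.csv in '%s'.", results_dir))
  results <- as_tibble(utils::read.csv(path))
  class(results) <- c("emg_experiment", class(results))
  summary <- summarize_results(results, wide = TRUE)
  normalized <- tryCatch(normalized_errors(results),
                         warning = function(w) {
                           warn(conditionMessage(w))
                           suppressWarnings(normalized_errors(results))
                         })
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(normalized, file.path(out_dir, "normalized_errors.csv"),
                   row.names = FALSE)
  invisible(list(summary = summary, normalized = normalized))
}
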