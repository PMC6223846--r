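# Experiment configuration: one structured object holding tank geometry, the
# trial schedule, the analysis windows, the generative behavior model and the
# analysis constants, with lossless YAML round-tripping.

default_analysis <- function() {
  list(
    fps = 30,
    band_hz = c(0.029, 0.146),
    circling_window_s = 30,
    tukey_alpha = 0.25,
    median_window = 5,
    n_last = 12,
    max_gap_frames = 5,
    margin_pre_s = 150,
    margin_post_s = 45,
    n_assignments = 10
  )
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ", section, " key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

#' Experiment configuration
#'
#' Bundles everything the pipeline needs; every field defaults to the
#' standard protocol values (20-min ITI, 9+9 alternating trials/day, 30-s
#' windows, 0.029-0.146 Hz circling band, surface threshold at 70% of the
#' water column, 5-trial median filter, d over the last 12 trials).
#'
#' @param geometry A [tank_geometry()] or a list of its arguments.
#' @param schedule A list of [trial_schedule()] arguments (not a built
#'   schedule); use [config_schedule()] to materialize it.
#' @param windows A [window_spec()] or argument list.
#' @param model A [behavior_model()] or argument list.
#' @param analysis List of analysis constants overriding the defaults
#'   (`fps`, `band_hz`, `circling_window_s`, `tukey_alpha`, `median_window`,
#'   `n_last`, `max_gap_frames`, `margin_pre_s`, `margin_post_s`,
#'   `n_assignments`).
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(geometry = list(), schedule = list(),
                              windows = list(), model = list(),
                              analysis = list()) {
  if (!inherits(geometry, "tank_geometry")) {
    check_args(geometry, tank_geometry, "geometry")
    geometry <- do.call(tank_geometry, geometry)
  }
  check_args(schedule, trial_schedule, "schedule")
  if (!inherits(windows, "window_spec")) {
    check_args(windows, window_spec, "windows")
    windows <- do.call(window_spec, windows)
  }
  if (!inherits(model, "behavior_model")) {
    check_args(model, behavior_model, "model")
    if (!is.null(model$response_gains))
      model$response_gains <- unlist(model$response_gains)
    model <- do.call(behavior_model, model)
  }
  analysis <- merge_section(default_analysis(), analysis, "analysis")
  if (analysis$band_hz[1] >= analysis$band_hz[2])
    stop("analysis band_hz must be increasing")
  if (analysis$fps <= 0) stop("fps must be positive")
  structure(list(geometry = geometry, schedule = schedule, windows = windows,
                 model = model, analysis = analysis),
            class = "experiment_config")
}

check_args <- function(user, constructor, section) {
  if (!is.list(user)) stop(section, " must be a list of arguments")
  unknown <- setdiff(names(user), names(formals(constructor)))
  if (length(unknown))
    stop("unknown ", section, " key(s): ", paste(unknown, collapse = ", "))
  invisible(user)
}

#' Materialize the trial schedule of a configuration
#' @param config An [experiment_config()].
#' @return A [trial_schedule()].
#' @export
config_schedule <- function(config) {
  sched <- config$schedule
  if (!is.null(sched$odors)) sched$odors <- unlist(sched$odors)
  do.call(trial_schedule, sched)
}

#' Save a configuration to YAML
#' @param config An [experiment_config()].
#' @param path Output file.
#' @export
save_config <- function(config, path) {
  plain <- list(
    geometry = unclass(config$geometry),
    schedule = config$schedule,
    windows = unclass(config$windows),
    model = unclass(config$model),
    analysis = config$analysis
  )
  plain$model$response_gains <- as.list(plain$model$response_gains)
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' Load a configuration from YAML
#'
#' Missing sections and keys fall back to the protocol defaults; unknown keys
#' are rejected with an error naming the key. An empty file yields the full
#' default configuration.
#'
#' @param path YAML file.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("geometry", "schedule", "windows", "model", "analysis")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  numify <- function(x) {
    if (is.list(x) && is.null(names(x)) &&
        all(vapply(x, is.numeric, TRUE))) unlist(x) else x
  }
  for (sec in names(raw)) raw[[sec]] <- lapply(raw[[sec]], numify)
  experiment_config(
    geometry = if (is.null(raw$geometry)) list() else raw$geometry,
    schedule = if (is.null(raw$schedule)) list() else raw$schedule,
    windows = if (is.null(raw$windows)) list() else raw$windows,
    model = if (is.null(raw$model)) list() else raw$model,
    analysis = if (is.null(raw$analysis)) list() else raw$analysis
  )
}
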