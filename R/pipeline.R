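# Table I/O and the umbrella pipeline: simulate -> parameters -> zeta scores
# -> composites -> learning/discrimination analysis, with a structured run
# report capturing config, seed and package version.

#' Write / read a trajectory as plain CSV
#'
#' Interchange format: header `fish_id,frame,t_s,x_cm,y_cm,z_cm`.
#'
#' @param traj A `fish_trajectory`.
#' @param path CSV file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("fish_id", "frame", "t_s",
                                           "x_cm", "y_cm", "z_cm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param fps Frame rate of the stored trajectory.
#' @export
read_trajectory <- function(path, fps = 30) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("fish_id", "frame", "t_s", "x_cm", "y_cm", "z_cm")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("trajectory file lacks column(s): ", paste(missing, collapse = ", "))
  structure(df[, needed], class = c("fish_trajectory", "data.frame"),
            fps = fps)
}

#' Score one fish end to end
#'
#' Computes the parameter panel, the zeta transform and per-trial composite
#' scores for a single trajectory.
#'
#' @param traj A `fish_trajectory`.
#' @param geometry A [tank_geometry()].
#' @param schedule A labeled [trial_schedule()].
#' @param windows A [window_spec()].
#' @param analysis Analysis constants (see [experiment_config()]).
#' @param shift_s Window shift in seconds (pre-odor control uses -60).
#' @return A composite `zeta_scores` table for this fish.
#' @export
score_trajectory <- function(traj, geometry, schedule,
                             windows = window_spec(),
                             analysis = default_analysis(), shift_s = 0) {
  panel <- compute_parameters(traj, geometry,
                              band_hz = analysis$band_hz,
                              window_s = analysis$circling_window_s,
                              tukey_alpha = analysis$tukey_alpha)
  zp <- zeta_transform(panel, schedule, windows, shift_s = shift_s)
  composite_scores(trial_scores(zp))
}

#' Simulate and score a cohort
#'
#' Streams fish one at a time (simulate, extract parameters, zeta-score,
#' discard the trajectory) and returns the combined per-trial composite
#' table, optionally together with the pre-odor-control scores computed from
#' the same trajectories.
#'
#' @param n_fish Cohort size.
#' @param config An [experiment_config()].
#' @param scenario Simulation scenario, see [simulate_cohort()].
#' @param seed Cohort seed.
#' @param preodor Also compute window-shifted control scores?
#' @return A list with `scores`, optionally `preodor_scores`, and the
#'   per-fish CS+ odor assignments.
#' @export
simulate_and_score <- function(n_fish, config = experiment_config(),
                               scenario = c("learning", "null", "unpaired"),
                               seed = 1, preodor = FALSE) {
  scenario <- match.arg(scenario)
  geometry <- config$geometry
  schedule <- config_schedule(config)
  windows <- config$windows
  analysis <- config$analysis
  model <- config$model
  if (scenario != "learning") model$response_gains[] <- 0
  set.seed(seed)
  fish_seeds <- sample.int(.Machine$integer.max - 1, n_fish)
  odors <- unique(schedule$odor)
  scores <- vector("list", n_fish)
  pre <- vector("list", n_fish)
  cs_plus <- character(n_fish)
  shift <- -(windows$baseline_s + windows$response_s)
  for (i in seq_len(n_fish)) {
    cs_plus[i] <- odors[1 + (i + 1) %% 2]
    sched_i <- assign_labels(schedule, cs_plus[i])
    traj <- simulate_fish(geometry, sched_i, model,
                          fps = analysis$fps,
                          margin_pre_s = analysis$margin_pre_s,
                          margin_post_s = analysis$margin_post_s,
                          fish_id = sprintf("fish%02d", i),
                          seed = fish_seeds[i])
    panel <- compute_parameters(traj, geometry,
                                band_hz = analysis$band_hz,
                                window_s = analysis$circling_window_s,
                                tukey_alpha = analysis$tukey_alpha)
    zp <- zeta_transform(panel, sched_i, windows)
    scores[[i]] <- composite_scores(trial_scores(zp))
    if (preodor) {
      zpc <- zeta_transform(panel, sched_i, windows, shift_s = shift)
      pre[[i]] <- composite_scores(trial_scores(zpc))
    }
  }
  out <- list(scores = do.call(rbind, scores),
              cs_plus = setNames(cs_plus, sprintf("fish%02d", seq_len(n_fish))),
              scenario = scenario, seed = seed)
  if (preodor) out$preodor_scores <- do.call(rbind, pre)
  out
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort under `config`, scores every trial, and produces the
#' learning curve, the discrimination score, and (depending on scenario) the
#' pre-odor and unpaired controls. All tables are written as CSV and a
#' structured JSON run report records the configuration, seeds, package
#' version and headline results, so a run can be reproduced bit-identically.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param n_fish Cohort size.
#' @param scenario `"learning"`, `"null"` or `"unpaired"`.
#' @param seed Master seed for the run.
#' @return Invisibly, a list with the scores table, `learning_curve`,
#'   `discrimination_result`, control results and the report.
#' @export
run_pipeline <- function(config = experiment_config(), out_dir = NULL,
                         n_fish = 12,
                         scenario = c("learning", "null", "unpaired"),
                         seed = 1) {
  scenario <- match.arg(scenario)
  analysis <- config$analysis
  run <- simulate_and_score(n_fish, config, scenario, seed = seed,
                            preodor = TRUE)
  curve <- learning_curve(run$scores)
  disc <- discrimination_score(run$scores, n_last = analysis$n_last)
  pre_disc <- discrimination_score(run$preodor_scores,
                                   n_last = analysis$n_last)
  unpaired <- NULL
  if (scenario == "unpaired") {
    unpaired <- unpaired_control(run$scores,
                                 n_assignments = analysis$n_assignments,
                                 seed = seed, n_last = analysis$n_last)
  }
  report <- list(
    package = "zebralearn",
    version = as.character(utils::packageVersion("zebralearn")),
    seed = seed,
    n_fish = n_fish,
    scenario = scenario,
    analysis = analysis,
    results = list(
      mean_d = disc$mean_d,
      sem_d = disc$sem_d,
      p_signed_rank = disc$p_signed_rank,
      p_pooled_ranksum = disc$p_pooled_ranksum,
      preodor_mean_d = pre_disc$mean_d,
      preodor_p_signed_rank = pre_disc$p_signed_rank,
      unpaired_mean_d = if (is.null(unpaired)) NULL else unpaired$mean_d,
      unpaired_sd_d = if (is.null(unpaired)) NULL else unpaired$sd_d
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(run$scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE)
    utils::write.csv(run$preodor_scores,
                     file.path(out_dir, "scores_preodor.csv"),
                     row.names = FALSE)
    utils::write.csv(curve$curve, file.path(out_dir, "learning_curve.csv"),
                     row.names = FALSE)
    save_config(config, file.path(out_dir, "config.yaml"))
    report$config_md5 <-
      unname(tools::md5sum(file.path(out_dir, "config.yaml")))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(scores = run$scores, preodor_scores = run$preodor_scores,
                 learning_curve = curve, discrimination = disc,
                 preodor = pre_disc, unpaired = unpaired, report = report))
}
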