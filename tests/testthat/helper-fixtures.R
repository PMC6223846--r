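# Shared fixtures. Cohort simulations are memoized so that several test files
# (and the acceptance checks) can share one realization instead of re-running
# the simulator.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Hand-built trajectory from coordinate vectors, frames on the fps grid.
make_traj <- function(x, y = rep(1, length(x)), z = rep(1, length(x)),
                      fps = 30, t0 = 0, fish_id = "f1") {
  n <- length(x)
  t_s <- t0 + (seq_len(n) - 1) / fps
  structure(
    data.frame(fish_id = fish_id, frame = as.integer(round(t_s * fps)),
               t_s = t_s, x_cm = x, y_cm = y, z_cm = z,
               stringsAsFactors = FALSE),
    class = c("fish_trajectory", "data.frame"), fps = fps)
}

# Hand-built wide parameter panel in which every parameter carries the same
# series; frames on the fps grid starting at t = 0.
make_panel <- function(values, fps = 1, fish_id = "f1") {
  n <- length(values)
  t_s <- (seq_len(n) - 1) / fps
  df <- data.frame(fish_id = fish_id, frame = as.integer(round(t_s * fps)),
                   t_s = t_s, stringsAsFactors = FALSE)
  for (p in c("Speed", "Zlevel", "Area", "Surface", "Distance", "Circling"))
    df[[p]] <- values
  structure(df, class = c("parameter_panel", "data.frame"), fps = fps)
}

# Schedule used by the hand-computed zeta oracle: fps = 1 Hz, 2-s windows.
toy_windows <- function() window_spec(baseline_s = 2, response_s = 2)

toy_schedule <- function(onsets = c(10, 30, 50, 70),
                         labels = c("CSplus", "CSplus", "CSminus", "CSminus")) {
  sched <- data.frame(trial = seq_along(onsets), day = 1,
                      odor = ifelse(labels == "CSplus", "A", "B"),
                      onset_s = onsets, food_delay_s = 2,
                      label = labels, stringsAsFactors = FALSE)
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

# Builds the panel realizing the hand-computed oracle: per trial, reference
# values r, baseline 0, response values v (constant over each 2-s window).
toy_oracle_panel <- function(ref = c(1, -1, 1, -1), resp = c(2, 2, 0, 0),
                             onsets = c(10, 30, 50, 70)) {
  values <- numeric(80)
  for (i in seq_along(onsets)) {
    o <- onsets[i] + 1  # frame o is at t = onsets[i] (1-based index)
    values[(o - 4):(o - 3)] <- ref[i]
    values[(o - 2):(o - 1)] <- 0
    values[o:(o + 1)] <- resp[i]
  }
  make_panel(values, fps = 1)
}

default_cfg <- function(...) experiment_config(...)

cohort_fixture <- function(n_fish, scenario, seed, days = 2, cfg = NULL,
                           preodor = FALSE) {
  key <- paste("cohort", n_fish, scenario, seed, days, preodor,
               is.null(cfg), sep = "_")
  memo(key, {
    if (is.null(cfg))
      cfg <- experiment_config(schedule = list(days = days))
    simulate_and_score(n_fish, cfg, scenario, seed = seed, preodor = preodor)
  })
}
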