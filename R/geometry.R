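#' Tank geometry for the conditioning arena
#'
#' Describes the physical coordinate frame of the training tank. The origin is
#' at the front-bottom-left corner; `x` runs along the long axis, `y` along the
#' short axis and `z` upward, all in centimetres. The defaults reproduce the
#' typical arena: a 29 x 9.5 cm footprint with a ~6 cm water column, a floating
#' feeding ring of ~4.5 cm diameter in a front corner, a water inflow tube at
#' half height near the front wall, and a rectangular reward zone that bounds
#' the feeding ring, spans the full short axis and covers about one third of
#' the footprint.
#'
#' @param length_cm Tank length (long axis, x), cm.
#' @param width_cm Tank width (short axis, y), cm.
#' @param water_height_cm Height of the water column, cm.
#' @param ring_center Feeding-ring centre, `c(x, y)` cm.
#' @param ring_radius_cm Feeding-ring radius, cm.
#' @param inflow_pos Opening of the inflow tube, `c(x, y, z)` cm.
#' @param reward_zone Axis-aligned rectangle `c(xmin, xmax, ymin, ymax)` cm.
#' @param surface_threshold_frac Fraction of the water column defining the
#'   surface-sampling threshold (default 0.70).
#'
#' @return An object of class `tank_geometry`.
#' @export
tank_geometry <- function(length_cm = 29,
                          width_cm = 9.5,
                          water_height_cm = 6,
                          ring_center = c(3, 3),
                          ring_radius_cm = 2.25,
                          inflow_pos = c(0.5, width_cm / 2, water_height_cm / 2),
                          reward_zone = c(0, length_cm / 3, 0, width_cm),
                          surface_threshold_frac = 0.70) {
  stopifnot(length_cm > 0, width_cm > 0, water_height_cm > 0,
            ring_radius_cm > 0, length(ring_center) == 2,
            length(inflow_pos) == 3, length(reward_zone) == 4)
  if (surface_threshold_frac <= 0 || surface_threshold_frac >= 1)
    stop("surface_threshold_frac must lie in (0, 1)")
  if (ring_center[1] < 0 || ring_center[1] > length_cm ||
      ring_center[2] < 0 || ring_center[2] > width_cm)
    stop("ring_center must lie inside the tank footprint")
  if (inflow_pos[1] < 0 || inflow_pos[1] > length_cm ||
      inflow_pos[2] < 0 || inflow_pos[2] > width_cm ||
      inflow_pos[3] < 0 || inflow_pos[3] > water_height_cm)
    stop("inflow_pos must lie inside the tank volume")
  if (reward_zone[1] >= reward_zone[2] || reward_zone[3] >= reward_zone[4])
    stop("reward_zone must be a non-degenerate rectangle c(xmin, xmax, ymin, ymax)")
  if (abs(reward_zone[3]) > 1e-9 || abs(reward_zone[4] - width_cm) > 1e-9)
    stop("reward_zone must span the full short axis of the tank")
  frac <- (reward_zone[2] - reward_zone[1]) * (reward_zone[4] - reward_zone[3]) /
    (length_cm * width_cm)
  if (frac < 0.25 || frac > 0.45)
    stop(sprintf(
      "reward_zone covers %.0f%% of the footprint; it should cover about one third",
      100 * frac))
  structure(list(
    length_cm = length_cm, width_cm = width_cm,
    water_height_cm = water_height_cm,
    ring_center = as.numeric(ring_center),
    ring_radius_cm = ring_radius_cm,
    inflow_pos = as.numeric(inflow_pos),
    reward_zone = as.numeric(reward_zone),
    surface_threshold_frac = surface_threshold_frac
  ), class = "tank_geometry")
}

#' @export
print.tank_geometry <- function(x, ...) {
  cat(sprintf("Tank geometry: %.1f x %.1f cm footprint, %.1f cm water column\n",
              x$length_cm, x$width_cm, x$water_height_cm))
  cat(sprintf("  feeding ring at (%.1f, %.1f), r = %.2f cm\n",
              x$ring_center[1], x$ring_center[2], x$ring_radius_cm))
  cat(sprintf("  inflow at (%.1f, %.1f, %.1f) cm\n",
              x$inflow_pos[1], x$inflow_pos[2], x$inflow_pos[3]))
  cat(sprintf("  reward zone x [%.1f, %.1f], y [%.1f, %.1f] cm\n",
              x$reward_zone[1], x$reward_zone[2],
              x$reward_zone[3], x$reward_zone[4]))
  cat(sprintf("  surface threshold at %.0f%% of water column\n",
              100 * x$surface_threshold_frac))
  invisible(x)
}

# Surface-sampling threshold in cm above the tank bottom.
surface_threshold_cm <- function(geometry) {
  geometry$surface_threshold_frac * geometry$water_height_cm
}

# Closed-boundary point-in-rectangle test for the reward zone.
in_reward_zone <- function(x, y, geometry) {
  rz <- geometry$reward_zone
  x >= rz[1] & x <= rz[2] & y >= rz[3] & y <= rz[4]
}

#' Trial schedule for differential conditioning
#'
#' Builds the default training protocol: on each day, `trials_per_day_per_stimulus`
#' presentations of each of two odors are delivered in alternating fashion at a
#' fixed inter-trial interval. The rewarded odor (CS+) is assigned per fish with
#' [assign_labels()]; the schedule itself carries only odor identities.
#'
#' @param days Number of training days.
#' @param trials_per_day_per_stimulus Presentations of each odor per day
#'   (default 9, i.e. 18 trials/day).
#' @param iti_s Inter-trial interval in seconds (default 1200 = 20 min).
#' @param food_delay_s Delay from odor onset to food delivery on rewarded
#'   trials, seconds; also the length of the response window.
#' @param odors Two odor identifiers.
#' @param first_odor Odor presented first each day.
#' @param day_start_s Time of the first onset within a day, seconds.
#' @param day_length_s Nominal length of a day, seconds (separates onsets of
#'   consecutive days on the absolute time axis).
#'
#' @return A `trial_schedule` data frame with columns `trial`, `day`, `odor`,
#'   `onset_s`, `food_delay_s`.
#' @export
trial_schedule <- function(days = 2,
                           trials_per_day_per_stimulus = 9,
                           iti_s = 1200,
                           food_delay_s = 30,
                           odors = c("A", "B"),
                           first_odor = odors[1],
                           day_start_s = 600,
                           day_length_s = 86400) {
  stopifnot(days >= 1, trials_per_day_per_stimulus >= 1, iti_s > 0,
            food_delay_s > 0, length(odors) == 2, first_odor %in% odors)
  per_day <- 2L * trials_per_day_per_stimulus
  other <- setdiff(odors, first_odor)
  odor_day <- rep(c(first_odor, other), trials_per_day_per_stimulus)
  sched <- do.call(rbind, lapply(seq_len(days), function(d) {
    data.frame(
      day = d,
      odor = odor_day,
      onset_s = (d - 1) * day_length_s + day_start_s + (seq_len(per_day) - 1) * iti_s,
      food_delay_s = food_delay_s,
      stringsAsFactors = FALSE
    )
  }))
  sched <- cbind(trial = seq_len(nrow(sched)), sched)
  if (any(diff(sched$onset_s) <= 0))
    stop("onset times must be strictly increasing")
  structure(sched,
            class = c("trial_schedule", "data.frame"),
            iti_s = iti_s,
            trials_per_day_per_stimulus = trials_per_day_per_stimulus)
}

#' Assign CS+/CS- labels to a schedule
#'
#' @param schedule A [trial_schedule()].
#' @param cs_plus The odor rewarded for this fish.
#' @return The schedule with an added `label` column (`"CSplus"`/`"CSminus"`).
#' @export
assign_labels <- function(schedule, cs_plus) {
  if (!cs_plus %in% schedule$odor)
    stop("cs_plus must be one of the odors in the schedule")
  schedule$label <- ifelse(schedule$odor == cs_plus, "CSplus", "CSminus")
  schedule
}

# Within-class (per-label) trial index, 1-based, used by the learning model
# and by the last-n-trials selection.
class_trial_index <- function(labels) {
  stats::ave(seq_along(labels), labels, FUN = seq_along)
}

#' Analysis time windows
#'
#' Three windows are used per trial: a baseline window ending at odor onset, a
#' response window from onset to food delivery, and a reference window of the
#' same length as the response window immediately preceding the baseline
#' window. Reference and response windows are therefore equidistant from the
#' baseline window.
#'
#' @param baseline_s Baseline window length, s (default 30).
#' @param response_s Response window length, s (default 30; the odor-to-food
#'   delay).
#' @param reference_s Reference window length, s; must equal `response_s`.
#' @return A `window_spec` object.
#' @export
window_spec <- function(baseline_s = 30, response_s = 30,
                        reference_s = response_s) {
  stopifnot(baseline_s > 0, response_s > 0)
  if (!isTRUE(all.equal(reference_s, response_s)))
    stop("the reference window must have the same length as the response window")
  structure(list(baseline_s = baseline_s, response_s = response_s,
                 reference_s = reference_s),
            class = "window_spec")
}

#' Generative behavior model for the trajectory simulator
#'
#' Parameterizes the stochastic locomotion model used by [simulate_fish()]:
#' wall-following circling at a baseline frequency, occasional burst swims,
#' and odor-evoked appetitive responses whose magnitude grows over trials.
#' The six response gains map onto the six behavioral parameters measured
#' downstream.
#'
#' @param baseline_circle_freq_hz Frequency of wall-following circling, Hz.
#'   The default (0.09) lies inside the 0.029-0.146 Hz band quantified by the
#'   circling index.
#' @param baseline_z_frac Resting height in the water column as a fraction of
#'   the water height.
#' @param response_gains Named numeric vector of non-negative appetitive
#'   response gains: `speed` (cm/s added during the response window), `zlevel`
#'   (fractional elevation of the height setpoint), `area` (reward-zone
#'   attraction; hover occupancy is `1 - exp(-area * u)`), `surface`
#'   (expected surface-sampling events per response window), `inflow`
#'   (0-1 pull of the hover point toward the inflow opening), `circling`
#'   (rate of swim-direction reversals that break the circling rhythm).
#' @param learning_rate Per-trial growth rate of the CS+ response; the learned
#'   fraction after the k-th trial of a class is `1 - exp(-learning_rate * k)`.
#'   Use `Inf` for instant learning, 0 for no learning.
#' @param cs_minus_gain_frac Fraction of the CS+ response expressed on CS-
#'   trials (generalization), in \[0, 1\].
#' @param noise_sd SD of the fast positional jitter, cm.
#' @param slow_sd_cm SD of the slow (tens of seconds) drift of the height
#'   setpoint, cm; the analogous speed drift is `slow_sd_speed_frac`.
#' @param slow_sd_speed_frac Fractional SD of the slow swimming-speed drift.
#' @param slow_tau_s Correlation time of the slow drifts, s.
#' @param sprint_rate_hz Rate of spontaneous burst swims, per second.
#' @param baseline_surface_rate_hz Rate of spontaneous surface-sampling
#'   excursions, per second.
#' @param seed Default RNG seed used by [simulate_fish()] when no seed is
#'   passed explicitly.
#'
#' @return A `behavior_model` object.
#' @export
behavior_model <- function(baseline_circle_freq_hz = 0.09,
                           baseline_z_frac = 0.45,
                           response_gains = c(speed = 0.3, zlevel = 0.035,
                                              area = 0.18, surface = 0.35,
                                              inflow = 0.15, circling = 0.35),
                           learning_rate = 1 / 9,
                           cs_minus_gain_frac = 0.1,
                           noise_sd = 0.12,
                           slow_sd_cm = 0.45,
                           slow_sd_speed_frac = 0.12,
                           slow_tau_s = 45,
                           sprint_rate_hz = 1 / 60,
                           baseline_surface_rate_hz = 0.008,
                           seed = NULL) {
  gains <- c(speed = 0, zlevel = 0, area = 0, surface = 0, inflow = 0,
             circling = 0)
  if (length(response_gains)) {
    if (is.null(names(response_gains)) ||
        !all(names(response_gains) %in% names(gains)))
      stop("response_gains must be named among: ",
           paste(names(gains), collapse = ", "))
    gains[names(response_gains)] <- response_gains
  }
  if (any(gains < 0)) stop("response gains must be non-negative")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (cs_minus_gain_frac < 0 || cs_minus_gain_frac > 1)
    stop("cs_minus_gain_frac must lie in [0, 1]")
  stopifnot(baseline_circle_freq_hz > 0, baseline_z_frac > 0,
            baseline_z_frac < 1, noise_sd >= 0)
  structure(list(
    baseline_circle_freq_hz = baseline_circle_freq_hz,
    baseline_z_frac = baseline_z_frac,
    response_gains = gains,
    learning_rate = learning_rate,
    cs_minus_gain_frac = cs_minus_gain_frac,
    noise_sd = noise_sd,
    slow_sd_cm = slow_sd_cm,
    slow_sd_speed_frac = slow_sd_speed_frac,
    slow_tau_s = slow_tau_s,
    sprint_rate_hz = sprint_rate_hz,
    baseline_surface_rate_hz = baseline_surface_rate_hz,
    seed = seed
  ), class = "behavior_model")
}

#' Learned response fraction after k trials
#'
#' @param model A [behavior_model()].
#' @param k Within-class trial index (1-based); vectorized.
#' @return The saturating learned fraction `1 - exp(-learning_rate * k)`.
#' @export
learned_fraction <- function(model, k) {
  r <- model$learning_rate
  if (is.infinite(r)) return(rep(1, length(k)))
  1 - exp(-r * k)
}
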