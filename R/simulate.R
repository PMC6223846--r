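# Synthetic trajectory generator.
#
# The locomotion model is a discrete-time stochastic state machine with three
# states: wall-following circling (with occasional burst sprints), hovering in
# the reward zone, and surface-sampling excursions under the feeding ring.
# Appetitive responses to the CS+ are expressed during the response window as
# (i) an additive speed increase, (ii) an elevated height setpoint, (iii)
# increased hover occupancy, (iv) Poisson surface-sampling events, (v) a pull
# of the hover point toward the inflow, and (vi) swim-direction reversals that
# disrupt the circling rhythm. Response magnitude grows over trials with a
# saturating learning curve; CS- trials express a configurable fraction of it.

# Wall-following track: an ellipse inset from the tank walls, parameterized by
# arc length so that advancing the arc coordinate at speed v yields swimming
# speed v. Returns interpolation tables and the perimeter.
make_track <- function(geometry, margin_cm = 1.5, n_grid = 4096) {
  a <- geometry$length_cm / 2 - margin_cm
  b <- geometry$width_cm / 2 - margin_cm
  if (a <= 0 || b <= 0) stop("tank too small for the wall-following track")
  cx <- geometry$length_cm / 2
  cy <- geometry$width_cm / 2
  theta <- seq(0, 2 * pi, length.out = n_grid + 1)
  x <- cx + a * cos(theta)
  y <- cy + b * sin(theta)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  list(arc = s, x = x, y = y, perimeter = s[length(s)])
}

track_xy <- function(track, arc) {
  arc <- arc %% track$perimeter
  cbind(x = stats::approx(track$arc, track$x, arc, rule = 2)$y,
        y = stats::approx(track$arc, track$y, arc, rule = 2)$y)
}

#' Expected mean swimming speed of the generator
#'
#' Closed-form expectation of the measured frame-to-frame speed for a fish in
#' the circling state: the baseline speed (circling frequency times track
#' perimeter) plus the additive speed response gain scaled by the learned
#' response strength `u`.
#'
#' @param model A [behavior_model()].
#' @param geometry A [tank_geometry()].
#' @param u Learned response strength in \[0, 1\] (0 = baseline).
#' @return Expected speed in cm/s.
#' @export
expected_mean_speed <- function(model, geometry, u = 0) {
  track <- make_track(geometry)
  model$baseline_circle_freq_hz * track$perimeter +
    model$response_gains[["speed"]] * u
}

# Temporally smooth Gaussian jitter: white noise convolved with a Gaussian
# kernel (circularly, to stay stationary) and rescaled to the target SD.
# Smoothness bounds the per-frame velocity the jitter contributes.
smooth_noise <- function(n, sd, fps, tau_s = 0.3) {
  if (sd <= 0) return(numeric(n))
  sigma <- max(1, tau_s * fps)
  half <- ceiling(3 * sigma)
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  z <- rnorm(n)
  sm <- as.numeric(stats::filter(z, k, sides = 2, circular = TRUE))
  sm * sd / sqrt(sum(k^2))
}

# Slow Ornstein-Uhlenbeck drift sampled at 1 Hz and interpolated to frames;
# provides the within-trial, window-to-window variability that the reference
# window of the zeta transform measures.
slow_drift <- function(n, sd, tau_s, fps) {
  if (sd <= 0) return(numeric(n))
  nsec <- ceiling(n / fps) + 1
  phi <- exp(-1 / tau_s)
  innov <- rnorm(nsec, sd = sd * sqrt(1 - phi^2))
  v <- numeric(nsec)
  v[1] <- rnorm(1, sd = sd)
  for (i in 2:nsec) v[i] <- phi * v[i - 1] + innov[i]
  stats::approx(seq_len(nsec), v, xout = 1 + (seq_len(n) - 1) / fps)$y
}

# Follow a target path with a maximum step length; between state switches the
# target moves slowly and the follower locks onto it exactly, so closed-form
# expectations for the circling state are preserved. State switches appear as
# burst swims toward the new target at the maximum speed.
pursue_target <- function(target, max_step) {
  n <- nrow(target)
  pos <- target
  step_len <- sqrt(rowSums((target[-1, , drop = FALSE] -
                              target[-n, , drop = FALSE])^2))
  jumps <- which(step_len > max_step) + 1L
  ji <- 1L
  while (ji <= length(jumps)) {
    i <- jumps[ji]
    cur <- pos[i - 1L, ]
    while (i <= n) {
      delta <- target[i, ] - cur
      dn <- sqrt(sum(delta^2))
      if (dn <= max_step) break
      cur <- cur + delta * (max_step / dn)
      pos[i, ] <- cur
      i <- i + 1L
    }
    while (ji <= length(jumps) && jumps[ji] <= i) ji <- ji + 1L
  }
  pos
}

#' Simulate one fish through a conditioning schedule
#'
#' Generates a 3D trajectory covering a peri-trial span around every odor
#' onset (by default 150 s before to 45 s after onset), sampled at exactly
#' `fps` frames per second. Behavior between these spans does not enter any
#' downstream statistic and is not simulated; the `t_s` column carries
#' absolute experiment time so the gaps are explicit.
#'
#' @param geometry A [tank_geometry()].
#' @param schedule A labeled [trial_schedule()] (see [assign_labels()]).
#' @param model A [behavior_model()].
#' @param fps Frame rate, Hz.
#' @param margin_pre_s Simulated seconds before each onset; must leave room
#'   for the reference, baseline and (shifted) response windows.
#' @param margin_post_s Simulated seconds after each onset.
#' @param fish_id Identifier stored in the trajectory.
#' @param seed RNG seed; defaults to the model's seed.
#'
#' @return A `fish_trajectory` data frame with columns
#'   `fish_id, frame, t_s, x_cm, y_cm, z_cm` and attribute `fps`.
#' @export
simulate_fish <- function(geometry, schedule, model, fps = 30,
                          margin_pre_s = 150, margin_post_s = 45,
                          fish_id = "fish1", seed = model$seed) {
  if (is.null(schedule$label))
    stop("schedule has no CS labels; call assign_labels() first")
  if (margin_pre_s < 90)
    stop("margin_pre_s must be at least 90 s to cover the reference, ",
         "baseline and response windows of every trial")
  iti <- min(diff(schedule$onset_s))
  if (iti < margin_pre_s + margin_post_s)
    stop("onsets closer than the simulated peri-trial span")
  if (!is.null(seed)) set.seed(seed)

  track <- make_track(geometry)
  v_base <- model$baseline_circle_freq_hz * track$perimeter
  wh <- geometry$water_height_cm
  thr <- surface_threshold_cm(geometry)
  gains <- model$response_gains
  max_step <- 30 / fps  # burst-swim ceiling, cm per frame
  k_class <- class_trial_index(schedule$label)

  n <- as.integer(round((margin_pre_s + margin_post_s) * fps))
  rel <- (seq_len(n) - 1) / fps - margin_pre_s
  arc0 <- runif(1, 0, track$perimeter)
  segs <- vector("list", nrow(schedule))

  for (i in seq_len(nrow(schedule))) {
    onset <- schedule$onset_s[i]
    resp_len <- schedule$food_delay_s[i]
    u <- learned_fraction(model, k_class[i]) *
      if (schedule$label[i] == "CSplus") 1 else model$cs_minus_gain_frac
    in_resp <- rel >= 0 & rel < resp_len

    # --- speed profile -----------------------------------------------------
    dv <- slow_drift(n, model$slow_sd_speed_frac, model$slow_tau_s, fps)
    v <- v_base * (1 + dv) + gains[["speed"]] * u * in_resp
    n_sprint <- rpois(1, model$sprint_rate_hz * (n / fps))
    if (n_sprint > 0) {
      for (t0 in runif(n_sprint, rel[1], rel[n])) {
        idx <- rel >= t0 & rel < t0 + 1.5
        v[idx] <- v[idx] * 2.5
      }
    }
    v <- pmax(v, 0.5)

    # --- circling-direction reversals during the response ------------------
    dir <- rep(1, n)
    rev_rate <- 0.15 * gains[["circling"]] * u
    if (rev_rate > 0) {
      n_rev <- rpois(1, rev_rate * resp_len)
      if (n_rev > 0) {
        for (t0 in sort(runif(n_rev, 0, resp_len))) {
          dir[rel >= t0] <- -dir[rel >= t0]
        }
      }
    }
    arc <- arc0 + cumsum(dir * v) / fps
    arc0 <- arc[n] %% track$perimeter
    xy <- track_xy(track, arc)

    # --- state schedule: hover and surface-sampling ------------------------
    state <- integer(n)  # 0 circle, 1 hover, 2 surface approach, 3 sampling
    p_h <- 1 - exp(-gains[["area"]] * u)
    if (p_h > 0) {
      # alternating exponential dwells over the response window
      tcur <- 0
      in_hover <- runif(1) < p_h
      while (tcur < resp_len) {
        dwell <- rexp(1, 1 / max(0.5, 7 * if (in_hover) p_h else 1 - p_h))
        if (in_hover) {
          idx <- rel >= tcur & rel < min(tcur + dwell, resp_len)
          state[idx] <- 1L
        }
        tcur <- tcur + dwell
        in_hover <- !in_hover
      }
    }
    n_ev <- rpois(1, gains[["surface"]] * u) +
      rpois(1, model$baseline_surface_rate_hz * (n / fps))
    if (n_ev > 0) {
      ev_resp <- runif(n_ev) < (gains[["surface"]] * u) /
        (gains[["surface"]] * u + model$baseline_surface_rate_hz * (n / fps))
      t_ev <- ifelse(ev_resp, runif(n_ev, 0, max(0.1, resp_len - 3)),
                     runif(n_ev, rel[1], rel[n] - 3))
      t_ev <- sort(t_ev)
      t_ev <- t_ev[c(TRUE, diff(t_ev) > 4)]  # enforce separation
      for (t0 in t_ev) {
        state[rel >= t0 & rel < t0 + 1.2] <- 2L          # approach, z held low
        state[rel >= t0 + 1.2 & rel < t0 + 2.2] <- 3L    # sampling above threshold
      }
    }

    # --- target path -------------------------------------------------------
    dz <- slow_drift(n, model$slow_sd_cm, model$slow_tau_s, fps)
    z_set <- model$baseline_z_frac * wh + dz +
      gains[["zlevel"]] * u * in_resp * wh
    z_set <- pmin(pmax(z_set, 0.35), thr - 0.7)

    hover_xy <- geometry$ring_center +
      min(1, gains[["inflow"]] * u) *
        (geometry$inflow_pos[1:2] - geometry$ring_center)
    tx <- xy[, 1]
    ty <- xy[, 2]
    tz <- z_set
    hov <- state == 1L
    if (any(hov)) {
      tx[hov] <- hover_xy[1] + smooth_noise(n, 0.6, fps, 0.5)[hov]
      ty[hov] <- hover_xy[2] + smooth_noise(n, 0.4, fps, 0.5)[hov]
      tz[hov] <- pmin(z_set[hov] + 0.2, thr - 0.7)
    }
    appr <- state == 2L
    samp <- state == 3L
    if (any(appr | samp)) {
      jx <- smooth_noise(n, 0.25, fps, 0.4)
      jy <- smooth_noise(n, 0.25, fps, 0.4)
      tx[appr | samp] <- geometry$ring_center[1] + jx[appr | samp]
      ty[appr | samp] <- geometry$ring_center[2] + jy[appr | samp]
      tz[appr] <- pmin(z_set[appr], thr - 0.8)
      tz[samp] <- min(thr + 0.4, wh - 0.1)
    }
    tx <- tx + smooth_noise(n, model$noise_sd, fps)
    ty <- ty + smooth_noise(n, model$noise_sd, fps)
    tz <- tz + smooth_noise(n, model$noise_sd, fps)

    pos <- pursue_target(cbind(tx, ty, tz), max_step)
    pos[, 1] <- pmin(pmax(pos[, 1], 0.05), geometry$length_cm - 0.05)
    pos[, 2] <- pmin(pmax(pos[, 2], 0.05), geometry$width_cm - 0.05)
    pos[, 3] <- pmin(pmax(pos[, 3], 0.05), wh - 0.05)

    t_abs <- onset + rel
    segs[[i]] <- data.frame(
      fish_id = fish_id,
      frame = as.integer(round(t_abs * fps)),
      t_s = t_abs,
      x_cm = pos[, 1], y_cm = pos[, 2], z_cm = pos[, 3],
      stringsAsFactors = FALSE
    )
  }
  traj <- do.call(rbind, segs)
  rownames(traj) <- NULL
  structure(traj, class = c("fish_trajectory", "data.frame"), fps = fps)
}

#' Frame rate of a trajectory
#' @param traj A `fish_trajectory`.
#' @return Frames per second.
#' @export
trajectory_fps <- function(traj) {
  fps <- attr(traj, "fps")
  if (is.null(fps)) stop("trajectory has no fps attribute")
  fps
}

#' Simulate a balanced cohort
#'
#' Simulates `n_fish` fish on the same schedule with the odor-to-CS+
#' assignment balanced across fish, under one of three scenarios:
#' `"learning"` uses the model as given; `"null"` and `"unpaired"` zero all
#' response gains, so CS+ and CS- trials are statistically identical (in the
#' unpaired design food arrives minutes after either odor with probability
#' 0.5 and no odor-locked response is acquired).
#'
#' @param n_fish Number of fish.
#' @param geometry,schedule,model,fps,margin_pre_s,margin_post_s Passed to
#'   [simulate_fish()]; `schedule` must be unlabeled (odors only).
#' @param scenario One of `"learning"`, `"null"`, `"unpaired"`.
#' @param seed Cohort seed; per-fish seeds are drawn from it.
#' @return A list with one element per fish:
#'   `list(trajectory, schedule, cs_plus)`.
#' @export
simulate_cohort <- function(n_fish, geometry, schedule, model,
                            scenario = c("learning", "null", "unpaired"),
                            seed = 1, fps = 30,
                            margin_pre_s = 150, margin_post_s = 45) {
  scenario <- match.arg(scenario)
  if (scenario != "learning") {
    model$response_gains[] <- 0
  }
  set.seed(seed)
  fish_seeds <- sample.int(.Machine$integer.max - 1, n_fish)
  odors <- unique(schedule$odor)
  lapply(seq_len(n_fish), function(i) {
    cs_plus <- odors[1 + (i + 1) %% 2]  # alternate: balanced assignment
    sched_i <- assign_labels(schedule, cs_plus)
    traj <- simulate_fish(geometry, sched_i, model, fps = fps,
                          margin_pre_s = margin_pre_s,
                          margin_post_s = margin_post_s,
                          fish_id = sprintf("fish%02d", i),
                          seed = fish_seeds[i])
    list(trajectory = traj, schedule = sched_i, cs_plus = cs_plus)
  })
}
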