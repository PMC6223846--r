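# The six behavioral parameters extracted from a 3D trajectory:
# Speed, Zlevel, Area, Surface, Distance, Circling.
#
# Trajectories may consist of several contiguous runs (e.g. peri-trial spans
# separated by unrecorded inter-trial time); Speed and Circling, which depend
# on temporal context, are computed per run and never across a gap.

# Indices of contiguous runs: a new run starts wherever the frame step
# exceeds 1 (frames are aligned to the fps grid).
trajectory_runs <- function(traj) {
  breaks <- which(diff(traj$frame) != 1L)
  list(starts = c(1L, breaks + 1L), ends = c(breaks, nrow(traj)))
}

check_uniform_sampling <- function(traj, fps, tol = 1e-6) {
  runs <- trajectory_runs(traj)
  for (r in seq_along(runs$starts)) {
    i <- runs$starts[r]:runs$ends[r]
    if (length(i) > 1) {
      dt <- diff(traj$t_s[i])
      if (any(abs(dt - 1 / fps) > tol))
        stop("non-uniform frame timestamps within a contiguous run")
    }
  }
  runs
}

#' Instantaneous swimming speed
#'
#' Euclidean 3D displacement between successive frames times the frame rate.
#' The first frame of each contiguous run is assigned the value of the second
#' frame so that the series stays frame-aligned with the trajectory.
#'
#' @param traj A `fish_trajectory`.
#' @return Speed in cm/s, one value per frame.
#' @export
compute_speed <- function(traj) {
  if (nrow(traj) < 2) stop("need at least two frames")
  fps <- trajectory_fps(traj)
  runs <- check_uniform_sampling(traj, fps)
  out <- numeric(nrow(traj))
  for (r in seq_along(runs$starts)) {
    i <- runs$starts[r]:runs$ends[r]
    if (length(i) == 1) { out[i] <- 0; next }
    d <- sqrt(diff(traj$x_cm[i])^2 + diff(traj$y_cm[i])^2 +
                diff(traj$z_cm[i])^2) * fps
    out[i] <- c(d[1], d)
  }
  out
}

#' Relative height in the water column
#'
#' `z / water_height`, clipped to \[0, 1\] (0 = tank bottom, 1 = surface).
#' Values above the surface (splashes) are clipped; the number of clipped
#' frames is reported as attribute `n_clipped`.
#'
#' @param traj A `fish_trajectory`.
#' @param geometry A [tank_geometry()].
#' @export
compute_zlevel <- function(traj, geometry) {
  raw <- traj$z_cm / geometry$water_height_cm
  n_clipped <- sum(raw < 0 | raw > 1)
  structure(pmin(pmax(raw, 0), 1), n_clipped = n_clipped)
}

#' Reward-zone residence
#'
#' Binary indicator: 1 when (x, y) lies inside the reward-zone rectangle
#' (closed boundaries), else 0.
#'
#' @inheritParams compute_zlevel
#' @export
compute_area <- function(traj, geometry) {
  as.numeric(in_reward_zone(traj$x_cm, traj$y_cm, geometry))
}

#' Surface-sampling events
#'
#' An event is an upward crossing of the surface threshold (a fixed fraction
#' of the water column) while the fish is horizontally within the feeding
#' ring. The series is 1 at the crossing frame and 0 elsewhere; after an
#' event, z must first fall below the threshold again before a new event can
#' be counted (hysteresis).
#'
#' @inheritParams compute_zlevel
#' @export
detect_surface_events <- function(traj, geometry) {
  thr <- surface_threshold_cm(geometry)
  above <- traj$z_cm >= thr
  # hysteresis: crossings are rising edges of the `above` state; run gaps
  # reset the state so an event cannot span unrecorded time
  runs <- trajectory_runs(traj)
  out <- numeric(nrow(traj))
  inside <- sqrt((traj$x_cm - geometry$ring_center[1])^2 +
                   (traj$y_cm - geometry$ring_center[2])^2) <=
    geometry$ring_radius_cm
  for (r in seq_along(runs$starts)) {
    i <- runs$starts[r]:runs$ends[r]
    a <- above[i]
    rising <- a & !c(FALSE, a[-length(a)])
    out[i][rising & inside[i]] <- 1
  }
  out
}

#' Distance to the inflow opening
#'
#' 3D Euclidean distance between the fish and the inflow tube opening, cm.
#'
#' @inheritParams compute_zlevel
#' @export
compute_distance_to_inflow <- function(traj, geometry) {
  p <- geometry$inflow_pos
  sqrt((traj$x_cm - p[1])^2 + (traj$y_cm - p[2])^2 + (traj$z_cm - p[3])^2)
}

# Relative spectral power of one contiguous x-position run, evaluated on 1-s
# bins with a centred sliding window (edge bins use the nearest full window).
circling_run <- function(x, fps, band_hz, window_s, tukey_alpha) {
  n <- length(x)
  nw <- as.integer(round(window_s * fps))
  if (n < nw) stop("trajectory run shorter than the spectral window")
  taper <- stats::spec.taper(rep(1, nw), p = tukey_alpha / 2)
  freq <- (seq_len(nw) - 1) / window_s  # two-sided FFT frequencies
  freq <- pmin(freq, fps - freq)        # fold to [0, Nyquist]
  in_band <- freq >= band_hz[1] & freq <= band_hz[2]
  n_bins <- max(1L, floor(n / fps))
  centers <- round(((seq_len(n_bins) - 1) + 0.5) * fps)
  starts <- pmin(pmax(centers - nw %/% 2, 0L), n - nw) + 1L
  idx <- outer(0:(nw - 1L), starts, "+")
  seg <- matrix(x[idx], nrow = nw)
  seg <- sweep(seg, 2, colMeans(seg)) * taper
  pw <- Mod(stats::mvfft(seg))^2
  total <- colSums(pw[-1, , drop = FALSE])   # exclude DC
  band <- colSums(pw[-1, , drop = FALSE][in_band[-1], , drop = FALSE])
  rel <- ifelse(total > 0, band / total, 0)
  # replicate bin values back to frames; trailing partial second reuses the
  # last bin
  rep(rel, times = diff(c((seq_len(n_bins) - 1) * fps, n)))[seq_len(n)]
}

#' Circling index
#'
#' Quantifies stereotyped wall-following swimming as the relative spectral
#' power of the long-axis (x) position in a low-frequency band. For each 1-s
#' bin, a window of `window_s` seconds centred on the bin is mean-detrended,
#' Tukey-tapered, and periodogram power inside `band_hz` is divided by total
#' non-DC power, giving a value in \[0, 1\]. Windows never span gaps between
#' contiguous runs.
#'
#' @param traj A `fish_trajectory`.
#' @param band_hz Frequency band, Hz (default 0.029-0.146).
#' @param window_s Spectral window length, s.
#' @param tukey_alpha Tukey taper shape parameter.
#' @return Relative band power per frame (constant within each 1-s bin).
#' @export
compute_circling <- function(traj, band_hz = c(0.029, 0.146), window_s = 30,
                             tukey_alpha = 0.25) {
  if (band_hz[1] >= band_hz[2]) stop("band_hz must be increasing")
  fps <- trajectory_fps(traj)
  runs <- check_uniform_sampling(traj, fps)
  out <- numeric(nrow(traj))
  for (r in seq_along(runs$starts)) {
    i <- runs$starts[r]:runs$ends[r]
    out[i] <- circling_run(traj$x_cm[i], fps, band_hz, window_s, tukey_alpha)
  }
  out
}

#' Compute the full behavioral parameter panel
#'
#' Evaluates all six parameters on a trajectory and returns them frame-aligned
#' in wide format. Use [panel_long()] for the tidy long interchange format.
#'
#' @inheritParams compute_circling
#' @param geometry A [tank_geometry()].
#' @return A `parameter_panel` data frame with columns `fish_id, frame, t_s,
#'   Speed, Zlevel, Area, Surface, Distance, Circling`.
#' @export
compute_parameters <- function(traj, geometry, band_hz = c(0.029, 0.146),
                               window_s = 30, tukey_alpha = 0.25) {
  panel <- data.frame(
    fish_id = traj$fish_id,
    frame = traj$frame,
    t_s = traj$t_s,
    Speed = compute_speed(traj),
    Zlevel = as.numeric(compute_zlevel(traj, geometry)),
    Area = compute_area(traj, geometry),
    Surface = detect_surface_events(traj, geometry),
    Distance = compute_distance_to_inflow(traj, geometry),
    Circling = compute_circling(traj, band_hz, window_s, tukey_alpha),
    stringsAsFactors = FALSE
  )
  structure(panel, class = c("parameter_panel", "data.frame"),
            fps = trajectory_fps(traj))
}

#' Long-format parameter panel
#'
#' @param panel A `parameter_panel`.
#' @return A tidy data frame `fish_id, frame, t_s, parameter, value`.
#' @export
panel_long <- function(panel) {
  long <- do.call(rbind, lapply(PARAMETERS, function(p) {
    data.frame(fish_id = panel$fish_id, frame = panel$frame, t_s = panel$t_s,
               parameter = p, value = panel[[p]], stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
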