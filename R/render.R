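# Synthetic two-view video rendering.
#
# Emulates the two orthogonal cameras: a top view imaging the (x, y) plane and
# a side view imaging the (x, z) plane. The fish is rendered as a bright
# anisotropic Gaussian blob on a dark background; images are padded by 1 cm of
# background on every side so that blobs near the walls are not truncated.

#' Pixel-to-cm calibration of one camera view
#'
#' Pixel `i` (1-based, first image axis = tank x) has its centre at
#' `(i - 0.5) / px_per_cm - pad_cm` in tank coordinates; the second image axis
#' maps to tank y (top view) or tank z (side view) with the same convention.
#'
#' @param view `"top"` or `"side"`.
#' @param px_per_cm Pixels per centimetre (isotropic).
#' @param pad_cm Background padding around the tank, cm.
#' @return A `view_calibration` object.
#' @export
view_calibration <- function(view = c("top", "side"), px_per_cm = 4,
                             pad_cm = 1) {
  view <- match.arg(view)
  stopifnot(px_per_cm > 0, pad_cm >= 0)
  structure(list(view = view, px_per_cm = px_per_cm, pad_cm = pad_cm),
            class = "view_calibration")
}

px_to_cm <- function(px, calib) (px - 0.5) / calib$px_per_cm - calib$pad_cm
cm_to_px <- function(cm, calib) (cm + calib$pad_cm) * calib$px_per_cm + 0.5

#' Render paired top/side view frames from a trajectory
#'
#' @param traj A `fish_trajectory`.
#' @param geometry A [tank_geometry()].
#' @param px_per_cm Image resolution.
#' @param fish_sd_cm Gaussian SD of the rendered fish along tank (x, y, z), cm.
#' @param noise_sd Optional additive Gaussian pixel noise.
#' @return A list with `top` and `side` image arrays
#'   (`x_px` x `other_px` x `n_frames`, intensities in \[0, 1\]) and the two
#'   calibrations.
#' @export
render_views <- function(traj, geometry, px_per_cm = 4,
                         fish_sd_cm = c(0.5, 0.3, 0.3), noise_sd = 0) {
  calib_top <- view_calibration("top", px_per_cm)
  calib_side <- view_calibration("side", px_per_cm)
  pad <- calib_top$pad_cm
  nx <- round((geometry$length_cm + 2 * pad) * px_per_cm)
  ny <- round((geometry$width_cm + 2 * pad) * px_per_cm)
  nz <- round((geometry$water_height_cm + 2 * pad) * px_per_cm)
  sd_px <- fish_sd_cm * px_per_cm
  if (any(4 * sd_px > c(nx, ny, nz)))
    stop("rendered fish larger than the image")
  n <- nrow(traj)
  top <- array(0, c(nx, ny, n))
  side <- array(0, c(nx, nz, n))
  gauss1d <- function(npx, center_px, sd) {
    exp(-0.5 * ((seq_len(npx) - center_px) / sd)^2)
  }
  for (i in seq_len(n)) {
    gx <- gauss1d(nx, cm_to_px(traj$x_cm[i], calib_top), sd_px[1])
    gy <- gauss1d(ny, cm_to_px(traj$y_cm[i], calib_top), sd_px[2])
    gz <- gauss1d(nz, cm_to_px(traj$z_cm[i], calib_side), sd_px[3])
    top[, , i] <- outer(gx, gy)
    side[, , i] <- outer(gx, gz)
  }
  if (noise_sd > 0) {
    top <- pmin(pmax(top + array(rnorm(length(top), sd = noise_sd),
                                 dim(top)), 0), 1)
    side <- pmin(pmax(side + array(rnorm(length(side), sd = noise_sd),
                                   dim(side)), 0), 1)
  }
  list(top = top, side = side,
       calibration = list(top = calib_top, side = calib_side),
       fps = trajectory_fps(traj))
}
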