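# Tracking: per-frame segmentation of each camera view and fusion of the two
# views into a 3D trajectory. Segmentation is background subtraction followed
# by Otsu thresholding (with an absolute floor) and connected-component
# labeling; the fish is represented by the intensity-weighted centre of
# gravity of the largest component.

#' Median background image
#'
#' Pixel-wise median over a subsample of frames; robust against the moving
#' fish as long as it does not dwell on one spot for most of the recording.
#'
#' @param frames An `x_px` x `y_px` x `n` image array.
#' @param n_sample Number of evenly spaced frames used for the median.
#' @return A background image matrix.
#' @export
median_background <- function(frames, n_sample = 50) {
  n <- dim(frames)[3]
  idx <- unique(round(seq(1, n, length.out = min(n_sample, n))))
  sub <- frames[, , idx, drop = FALSE]
  apply(sub, c(1, 2), median)
}

#' Segment one frame
#'
#' Background-subtracts, thresholds (Otsu with an absolute floor) and labels
#' connected components; returns the intensity-weighted centroid of the
#' largest component with area at least `min_area_px`. A frame in which no
#' component passes the area filter yields an invalid detection, not an error.
#'
#' @param frame,background Image matrices of identical size, intensities in
#'   \[0, 1\].
#' @param min_area_px Minimum component area in pixels.
#' @param threshold_floor Lower bound on the threshold, guarding against Otsu
#'   splitting pure background noise.
#' @return A list `(centroid_px, area_px, valid)`; `centroid_px` is `c(NA,
#'   NA)` when invalid.
#' @export
segment_frame <- function(frame, background, min_area_px = 5,
                          threshold_floor = 0.1) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background must have the same dimensions")
  diffim <- pmin(pmax(frame - background, 0), 1)
  invalid <- list(centroid_px = c(NA_real_, NA_real_), area_px = 0L,
                  valid = FALSE)
  if (max(diffim) <= threshold_floor) return(invalid)
  thr <- max(EBImage::otsu(EBImage::Image(diffim)), threshold_floor)
  mask <- diffim > thr
  if (!any(mask)) return(invalid)
  lbl <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  areas <- tabulate(lbl[lbl > 0])
  keep <- which(areas >= min_area_px)
  if (!length(keep)) return(invalid)
  comp <- keep[which.max(areas[keep])]
  sel <- lbl == comp
  w <- diffim[sel]
  idx <- which(sel, arr.ind = TRUE)
  list(centroid_px = c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w),
       area_px = as.integer(areas[comp]),
       valid = TRUE)
}

#' Segment every frame of a view
#'
#' @param frames Image array (`x_px` x `other_px` x `n`).
#' @param background Background matrix; computed with [median_background()]
#'   when `NULL`.
#' @inheritParams segment_frame
#' @return A data frame `frame, c1_px, c2_px, area_px, valid`.
#' @export
segment_frames <- function(frames, background = NULL, min_area_px = 5,
                           threshold_floor = 0.1) {
  if (is.null(background)) background <- median_background(frames)
  n <- dim(frames)[3]
  out <- data.frame(frame = seq_len(n), c1_px = NA_real_, c2_px = NA_real_,
                    area_px = 0L, valid = FALSE)
  for (i in seq_len(n)) {
    det <- segment_frame(frames[, , i], background, min_area_px,
                         threshold_floor)
    out$c1_px[i] <- det$centroid_px[1]
    out$c2_px[i] <- det$centroid_px[2]
    out$area_px[i] <- det$area_px
    out$valid[i] <- det$valid
  }
  out
}

#' Fuse top- and side-view detections into a 3D trajectory
#'
#' Takes x and y from the top view and z from the side view; the side-view x
#' coordinate is used only as a consistency check (frames where the two views
#' disagree by more than `x_tol_cm` are flagged and the top view is trusted).
#' Invalid detections are linearly interpolated up to `max_gap_frames`
#' consecutive frames; longer gaps remain `NA` and are flagged.
#'
#' @param top,side Detection data frames from [segment_frames()], frame
#'   aligned and of equal length.
#' @param calibration List with `top` and `side` [view_calibration()]s.
#' @param fps Frame rate.
#' @param max_gap_frames Longest gap to interpolate.
#' @param x_tol_cm Allowed top/side disagreement on the shared x axis.
#' @param fish_id Identifier for the output trajectory.
#' @return A `fish_trajectory` with attribute `quality` (per-frame flags
#'   `interpolated`, `long_gap`, `x_disagree`).
#' @export
fuse_views <- function(top, side, calibration, fps = 30, max_gap_frames = 5,
                       x_tol_cm = 0.5, fish_id = "fish1") {
  if (nrow(top) != nrow(side))
    stop("top and side detection sequences must have equal length")
  x <- ifelse(top$valid, px_to_cm(top$c1_px, calibration$top), NA_real_)
  y <- ifelse(top$valid, px_to_cm(top$c2_px, calibration$top), NA_real_)
  z <- ifelse(side$valid, px_to_cm(side$c2_px, calibration$side), NA_real_)
  x_side <- ifelse(side$valid, px_to_cm(side$c1_px, calibration$side),
                   NA_real_)
  disagree <- !is.na(x) & !is.na(x_side) & abs(x - x_side) > x_tol_cm

  fill <- function(v) {
    zoo::na.approx(v, na.rm = FALSE, maxgap = max_gap_frames)
  }
  missing_before <- is.na(x) | is.na(y) | is.na(z)
  x <- fill(x); y <- fill(y); z <- fill(z)
  long_gap <- is.na(x) | is.na(y) | is.na(z)
  interpolated <- missing_before & !long_gap

  n <- nrow(top)
  traj <- data.frame(
    fish_id = fish_id,
    frame = seq_len(n),
    t_s = (seq_len(n) - 1) / fps,
    x_cm = x, y_cm = y, z_cm = z,
    stringsAsFactors = FALSE
  )
  structure(traj, class = c("fish_trajectory", "data.frame"), fps = fps,
            quality = data.frame(frame = seq_len(n),
                                 interpolated = interpolated,
                                 long_gap = long_gap,
                                 x_disagree = disagree))
}

#' Track a pair of rendered (or recorded) views
#'
#' Convenience wrapper: median background per view, per-frame segmentation,
#' and view fusion.
#'
#' @param views A list as returned by [render_views()] (`top`, `side`,
#'   `calibration`, `fps`).
#' @inheritParams fuse_views
#' @inheritParams segment_frame
#' @return A `fish_trajectory`.
#' @export
track_views <- function(views, min_area_px = 5, threshold_floor = 0.1,
                        max_gap_frames = 5, x_tol_cm = 0.5,
                        fish_id = "fish1") {
  top <- segment_frames(views$top, min_area_px = min_area_px,
                        threshold_floor = threshold_floor)
  side <- segment_frames(views$side, min_area_px = min_area_px,
                         threshold_floor = threshold_floor)
  fuse_views(top, side, views$calibration, fps = views$fps,
             max_gap_frames = max_gap_frames, x_tol_cm = x_tol_cm,
             fish_id = fish_id)
}
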