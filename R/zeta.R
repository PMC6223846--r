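# Zeta scoring: transform behavioral parameter time series into trial-aligned,
# baseline-subtracted, class-mean-centred series normalized to pre-stimulus
# variability, then reduce to per-trial scalars and composite scores.

#' Zeta transform of a parameter panel
#'
#' For every trial and parameter, the transform applies three steps per fish:
#' (1) subtract that trial's mean over the baseline window; (2) average the
#' series over all CS+ trials and over all CS- trials and subtract the mean of
#' these two class averages from every trial's series; (3) divide all series
#' by the standard deviation (across all trials, both classes pooled, n-1
#' denominator) of the time-averaged values in the reference window. The
#' resulting family of series is centred on zero at every time point and
#' normalized to trial-to-trial variability in the absence of stimulation.
#' Signs for `Distance` and `Circling` are inverted so that positive zeta
#' always means "more appetitive than the mean".
#'
#' @param panel A `parameter_panel` (see [compute_parameters()]).
#' @param schedule A labeled [trial_schedule()].
#' @param windows A [window_spec()].
#' @param shift_s Shift applied to all three windows, seconds; `-60` with the
#'   default 30-s windows reproduces the pre-odor control in which the window
#'   60-30 s before odor onset serves as the response window.
#' @return A `zeta_panel`: trial x time x parameter array of zeta series plus
#'   trial metadata.
#' @export
zeta_transform <- function(panel, schedule, windows = window_spec(),
                           shift_s = 0) {
  if (is.null(schedule$label))
    stop("schedule has no CS labels; call assign_labels() first")
  if (any(table(schedule$label) < 2))
    stop("need at least two trials per stimulus class")
  fps <- attr(panel, "fps")
  if (is.null(fps)) stop("panel has no fps attribute")
  n_ref <- as.integer(round(windows$reference_s * fps))
  n_base <- as.integer(round(windows$baseline_s * fps))
  n_resp <- as.integer(round(windows$response_s * fps))
  n_pre <- n_ref + n_base
  n_rel <- n_pre + n_resp
  rel_t <- (seq_len(n_rel) - 1 - n_pre) / fps

  onset_frames <- as.integer(round((schedule$onset_s + shift_s) * fps))
  offsets <- seq.int(-n_pre, n_resp - 1L)
  n_trials <- nrow(schedule)
  idx <- matrix(NA_integer_, n_trials, n_rel)
  frame_lookup <- match(outer(onset_frames, offsets, "+"), panel$frame)
  idx[] <- frame_lookup
  if (anyNA(idx)) {
    bad <- schedule$trial[rowSums(is.na(idx)) > 0]
    stop("panel does not cover the reference+baseline+response windows of ",
         "trial(s) ", paste(bad, collapse = ", "),
         " (is margin_pre_s large enough?)")
  }

  ref_cols <- seq_len(n_ref)
  base_cols <- n_ref + seq_len(n_base)
  plus <- schedule$label == "CSplus"

  zeta <- array(NA_real_, c(n_trials, n_rel, length(PARAMETERS)),
                dimnames = list(NULL, NULL, PARAMETERS))
  for (p in PARAMETERS) {
    M <- matrix(panel[[p]][idx], n_trials, n_rel)
    M <- M - rowMeans(M[, base_cols, drop = FALSE])
    class_center <- (colMeans(M[plus, , drop = FALSE]) +
                       colMeans(M[!plus, , drop = FALSE])) / 2
    M <- sweep(M, 2, class_center)
    ref_avg <- rowMeans(M[, ref_cols, drop = FALSE])
    s <- sd(ref_avg)
    if (!is.finite(s) || s == 0)
      stop("reference-window variability is zero for parameter '", p,
           "' (degenerate fish)")
    M <- M / s
    if (p %in% INVERTED_PARAMETERS) M <- -M
    zeta[, , p] <- M
  }
  structure(list(
    zeta = zeta,
    rel_t = rel_t,
    trial = schedule$trial,
    day = schedule$day,
    label = schedule$label,
    odor = schedule$odor,
    fish_id = panel$fish_id[1],
    windows = windows,
    sign_inverted = INVERTED_PARAMETERS,
    fps = fps
  ), class = "zeta_panel")
}

#' Per-trial zeta scores
#'
#' Time-averages each zeta series over the response window, yielding one
#' scalar per trial and parameter (the "trial series" of zeta scores).
#'
#' @param zpanel A `zeta_panel`.
#' @return A `zeta_scores` data frame: `fish_id, trial, day, label, odor` plus
#'   one column per behavioral parameter.
#' @export
trial_scores <- function(zpanel) {
  resp <- zpanel$rel_t >= 0
  out <- data.frame(fish_id = zpanel$fish_id, trial = zpanel$trial,
                    day = zpanel$day, label = zpanel$label,
                    odor = zpanel$odor, stringsAsFactors = FALSE)
  for (p in PARAMETERS) {
    out[[p]] <- rowMeans(zpanel$zeta[, resp, p, drop = FALSE])
  }
  structure(out, class = c("zeta_scores", "data.frame"))
}

# Extract the trials x parameters matrix from a zeta_scores table.
score_matrix <- function(scores) {
  missing <- setdiff(PARAMETERS, names(scores))
  if (length(missing))
    stop("missing parameter column(s): ", paste(missing, collapse = ", "))
  as.matrix(scores[, PARAMETERS])
}

#' Stouffer composite score
#'
#' Combines the six per-parameter zeta scores of a trial into a single
#' composite appetitive score: the sum of the scores divided by the square
#' root of their number (6), following Stouffer's method for combining
#' z-scores.
#'
#' @param scores A numeric vector of the six parameter scores, or a matrix /
#'   `zeta_scores` table with one column per parameter (rows = trials).
#' @return The composite score(s).
#' @export
stouffer_composite <- function(scores) {
  if (is.data.frame(scores)) scores <- score_matrix(scores)
  if (is.null(dim(scores))) {
    if (length(scores) != length(PARAMETERS))
      stop("expected exactly ", length(PARAMETERS), " parameter scores")
    return(sum(scores) / sqrt(length(scores)))
  }
  if (ncol(scores) != length(PARAMETERS))
    stop("expected exactly ", length(PARAMETERS), " parameter columns")
  rowSums(scores) / sqrt(ncol(scores))
}

#' Covariance-weighted composite score
#'
#' Weights each parameter by the ratio of its auto-covariance to the sum of
#' its auto- and cross-covariances, `w_i = C_ii / sum_j C_ij`, discounting
#' redundant parameters, and renormalizes by `sqrt(sum(w_i^2))` so that the
#' weighted composite reduces exactly to the Stouffer composite when the
#' covariance is diagonal with equal variances.
#'
#' @param scores Trials x parameters matrix (or `zeta_scores` table).
#' @param covariance 6 x 6 parameter covariance matrix, typically estimated
#'   from a cohort with [cohort_covariance()].
#' @return Per-trial weighted composite scores, with the weights as attribute
#'   `weights`.
#' @export
weighted_composite <- function(scores, covariance) {
  if (is.data.frame(scores)) scores <- score_matrix(scores)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  k <- length(PARAMETERS)
  if (!all(dim(covariance) == c(k, k)))
    stop("covariance must be ", k, " x ", k)
  row_sums <- rowSums(covariance)
  if (any(row_sums <= 0))
    stop("degenerate weighting: auto- plus cross-covariances are <= 0 for ",
         "parameter(s) ",
         paste(PARAMETERS[row_sums <= 0], collapse = ", "))
  w <- diag(covariance) / row_sums
  out <- as.numeric(scores %*% w) / sqrt(sum(w^2))
  structure(out, weights = setNames(w, PARAMETERS))
}

#' Pooled parameter covariance over a cohort
#'
#' Covariance of the six trial-score series, computed per fish and averaged
#' over fish.
#'
#' @param cohort_scores A list of `zeta_scores` tables (one per fish) or a
#'   single combined table with a `fish_id` column.
#' @return A 6 x 6 covariance matrix.
#' @export
cohort_covariance <- function(cohort_scores) {
  mats <- cohort_score_matrices(cohort_scores)
  covs <- lapply(mats, function(m) stats::cov(m))
  Reduce(`+`, covs) / length(covs)
}

cohort_score_matrices <- function(cohort_scores) {
  if (is.data.frame(cohort_scores)) {
    split_scores <- split(cohort_scores, cohort_scores$fish_id)
    mats <- lapply(split_scores, score_matrix)
  } else {
    mats <- lapply(cohort_scores, function(s) {
      if (is.data.frame(s)) score_matrix(s) else as.matrix(s)
    })
  }
  mats
}

#' Mean trial-by-trial parameter correlation matrix
#'
#' Pearson correlations between the trial-score series of each parameter
#' pair, computed within each fish and averaged over fish. Fish in which a
#' parameter's series has zero variance are excluded from that pair's
#' average; the number of fish contributing to each entry is returned as
#' attribute `n_fish`.
#'
#' @inheritParams cohort_covariance
#' @return A 6 x 6 mean correlation matrix with unit diagonal.
#' @export
parameter_correlations <- function(cohort_scores) {
  mats <- cohort_score_matrices(cohort_scores)
  if (any(vapply(mats, nrow, 1L) < 2))
    stop("need at least two trials per fish")
  k <- length(PARAMETERS)
  acc <- matrix(0, k, k)
  cnt <- matrix(0, k, k)
  for (m in mats) {
    sds <- apply(m, 2, sd)
    ok <- sds > 0
    if (sum(ok) < 2) next
    cc <- suppressWarnings(stats::cor(m))
    use <- outer(ok, ok) > 0
    acc[use] <- acc[use] + cc[use]
    cnt[use] <- cnt[use] + 1
  }
  out <- ifelse(cnt > 0, acc / cnt, NA_real_)
  diag(out) <- 1
  dimnames(out) <- list(PARAMETERS, PARAMETERS)
  structure(out, n_fish = cnt)
}
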