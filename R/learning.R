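# Learning curves, the discrimination score d, and the two negative controls
# (pre-odor window shift; unpaired food delivery with random balanced CS
# relabeling).

#' Composite scores per trial
#'
#' Adds the Stouffer composite `zeta_comp` (and, when a covariance matrix is
#' supplied, the covariance-weighted `zeta_comp_weighted`) to a table of
#' per-trial parameter zeta scores.
#'
#' @param scores A `zeta_scores` table (single fish or combined cohort).
#' @param covariance Optional 6 x 6 parameter covariance for the weighted
#'   composite.
#' @return The table with composite column(s) appended.
#' @export
composite_scores <- function(scores, covariance = NULL) {
  scores$zeta_comp <- stouffer_composite(scores)
  if (!is.null(covariance))
    scores$zeta_comp_weighted <-
      as.numeric(weighted_composite(scores, covariance))
  scores
}

rank_sum_p <- function(x, y) {
  if (!length(x) || !length(y)) return(NA_real_)
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

signed_rank_p <- function(d) {
  if (length(d) < 2 || all(d == 0)) return(NA_real_)
  suppressWarnings(stats::wilcox.test(d)$p.value)
}

#' Daily learning curve
#'
#' For each fish, day and stimulus class, takes the median composite score
#' over that day's trials, then averages the medians over fish (mean and
#' SEM). Each day is additionally tested with a two-sample rank-sum test
#' comparing all individual CS+ and CS- trials of that day, pooled over fish;
#' days are flagged at p < 0.05 and p < 0.01. No correction for multiple
#' days is applied.
#'
#' @param comp Cohort table from [composite_scores()] (with `fish_id`).
#' @param value Column to analyse, default `"zeta_comp"`.
#' @return A `learning_curve` object: per day x class mean, SEM, n and the
#'   per-day p values and flags.
#' @export
learning_curve <- function(comp, value = "zeta_comp") {
  v <- comp[[value]]
  med <- stats::aggregate(v,
    by = list(fish_id = comp$fish_id, day = comp$day, label = comp$label),
    FUN = median)
  curve <- do.call(rbind, lapply(split(med, list(med$day, med$label),
                                       drop = TRUE), function(g) {
    data.frame(day = g$day[1], label = g$label[1],
               mean = mean(g$x),
               sem = if (nrow(g) > 1) sd(g$x) / sqrt(nrow(g)) else NA_real_,
               n_fish = nrow(g), stringsAsFactors = FALSE)
  }))
  curve <- curve[order(curve$day, curve$label), ]
  rownames(curve) <- NULL
  days <- sort(unique(comp$day))
  day_p <- vapply(days, function(d) {
    rank_sum_p(v[comp$day == d & comp$label == "CSplus"],
               v[comp$day == d & comp$label == "CSminus"])
  }, numeric(1))
  structure(list(
    curve = curve,
    day_tests = data.frame(day = days, p = day_p,
                           sig05 = !is.na(day_p) & day_p < 0.05,
                           sig01 = !is.na(day_p) & day_p < 0.01),
    value = value
  ), class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("Learning curve (", x$value, "), per-day medians averaged over fish\n",
      sep = "")
  print(x$curve, digits = 3)
  cat("Per-day CS+ vs CS- rank-sum tests:\n")
  print(x$day_tests, digits = 3)
  invisible(x)
}

#' Plot a learning curve
#'
#' Mean daily medians per class with SEM bars; days with p < 0.05 (open) and
#' p < 0.01 (filled) are marked.
#'
#' @param x A `learning_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.learning_curve <- function(x, ...) {
  cv <- x$curve
  ylim <- range(c(cv$mean - cv$sem, cv$mean + cv$sem), na.rm = TRUE)
  plus <- cv[cv$label == "CSplus", ]
  minus <- cv[cv$label == "CSminus", ]
  graphics::plot(plus$day, plus$mean, type = "b", pch = 16, ylim = ylim,
                 xlab = "training day", ylab = x$value, ...)
  graphics::lines(minus$day, minus$mean, type = "b", pch = 1)
  for (g in list(plus, minus)) {
    ok <- !is.na(g$sem)
    graphics::arrows(g$day[ok], g$mean[ok] - g$sem[ok],
                     g$day[ok], g$mean[ok] + g$sem[ok],
                     angle = 90, code = 3, length = 0.03)
  }
  sig <- x$day_tests
  ytop <- ylim[2]
  graphics::points(sig$day[sig$sig05 & !sig$sig01],
                   rep(ytop, sum(sig$sig05 & !sig$sig01)), pch = 1)
  graphics::points(sig$day[sig$sig01], rep(ytop, sum(sig$sig01)), pch = 16)
  graphics::legend("topleft", legend = c("CS+", "CS-"), pch = c(16, 1),
                   bty = "n")
  invisible(x)
}

#' Centred running median over a trial series
#'
#' Median filter with an odd window (default five trials), applied per
#' stimulus class to suppress outlier trials. The filtered series is shorter
#' by `(window - 1) / 2` trials at each end; no padding is used.
#'
#' @param x Numeric trial series.
#' @param window Odd window size >= 3.
#' @return The filtered, trimmed series.
#' @export
median_filter_trials <- function(x, window = 5) {
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  n <- length(x)
  if (n < window) stop("need at least ", window, " trials")
  half <- (window - 1) / 2
  stats::runmed(x, window, endrule = "keep")[(half + 1):(n - half)]
}

#' Single-trial learning curve
#'
#' Orders each fish's composite scores by within-class trial number, median
#' filters each class's series ([median_filter_trials()]; the first and last
#' `(window-1)/2` trials are thereby omitted), then averages over fish and
#' tests CS+ against CS- across fish at each trial position (rank-sum).
#'
#' @inheritParams learning_curve
#' @param window Median-filter window.
#' @return A data frame per class trial position and label: mean, SEM, n, p.
#' @export
trial_curve <- function(comp, value = "zeta_comp", window = 5) {
  half <- (window - 1) / 2
  per_fish <- lapply(split(comp, comp$fish_id), function(g) {
    g <- g[order(g$trial), ]
    out <- list()
    for (lab in c("CSplus", "CSminus")) {
      v <- g[[value]][g$label == lab]
      f <- median_filter_trials(v, window)
      out[[lab]] <- data.frame(fish_id = g$fish_id[1], label = lab,
                               class_trial = half + seq_along(f), value = f,
                               stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  filt <- do.call(rbind, per_fish)
  agg <- do.call(rbind, lapply(split(filt, list(filt$class_trial, filt$label),
                                     drop = TRUE), function(g) {
    data.frame(class_trial = g$class_trial[1], label = g$label[1],
               mean = mean(g$value),
               sem = if (nrow(g) > 1) sd(g$value) / sqrt(nrow(g)) else NA_real_,
               n_fish = nrow(g), stringsAsFactors = FALSE)
  }))
  positions <- sort(unique(filt$class_trial))
  pvals <- vapply(positions, function(k) {
    rank_sum_p(filt$value[filt$class_trial == k & filt$label == "CSplus"],
               filt$value[filt$class_trial == k & filt$label == "CSminus"])
  }, numeric(1))
  agg$p <- pvals[match(agg$class_trial, positions)]
  agg <- agg[order(agg$class_trial, agg$label), ]
  rownames(agg) <- NULL
  agg
}

#' Discrimination score d
#'
#' Per fish, `d` is the mean composite score over the last `n_last` CS+
#' trials minus the mean over the last `n_last` CS- trials. The cohort is
#' summarized by mean and SEM of d, a one-sample Wilcoxon signed-rank test of
#' d against zero, and a pooled two-sample rank-sum test comparing all
#' individual CS+ and CS- trials in the table.
#'
#' @inheritParams learning_curve
#' @param n_last Number of trials per class entering d (default 12).
#' @return A `discrimination_result`.
#' @export
discrimination_score <- function(comp, n_last = 12, value = "zeta_comp") {
  per_fish <- split(comp, comp$fish_id)
  d <- vapply(per_fish, function(g) {
    g <- g[order(g$trial), ]
    vp <- g[[value]][g$label == "CSplus"]
    vm <- g[[value]][g$label == "CSminus"]
    if (length(vp) < n_last || length(vm) < n_last)
      stop("fish ", g$fish_id[1], " has fewer than ", n_last,
           " trials in a class")
    mean(utils::tail(vp, n_last)) - mean(utils::tail(vm, n_last))
  }, numeric(1))
  n <- length(d)
  structure(list(
    d_per_fish = d,
    mean_d = mean(d),
    sem_d = if (n > 1) sd(d) / sqrt(n) else NA_real_,
    n_fish = n,
    p_signed_rank = signed_rank_p(d),
    p_pooled_ranksum = rank_sum_p(comp[[value]][comp$label == "CSplus"],
                                  comp[[value]][comp$label == "CSminus"]),
    n_last = n_last,
    value = value
  ), class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "Discrimination score d = %.3f +/- %.3f (mean +/- SEM, n = %d fish)\n",
    x$mean_d, x$sem_d, x$n_fish))
  cat(sprintf("  signed-rank test d vs 0: p = %.3g\n", x$p_signed_rank))
  cat(sprintf("  pooled CS+ vs CS- rank-sum: p = %.3g\n", x$p_pooled_ranksum))
  invisible(x)
}

#' Pre-odor window-shift control
#'
#' Re-runs the full zeta pipeline with all three analysis windows shifted
#' 60 s earlier (for 30-s windows), so that the window 60-30 s before odor
#' onset serves as the response window. Any apparent discrimination in this
#' re-analysis would indicate a bias in the procedure rather than
#' odor-evoked behavior.
#'
#' @param panels List of `parameter_panel`s, one per fish.
#' @param schedules A single labeled schedule or a list parallel to `panels`
#'   (labels usually differ between fish because odor assignments are
#'   balanced).
#' @param windows A [window_spec()].
#' @param n_last Trials per class entering d.
#' @return A `discrimination_result` for the shifted windows.
#' @export
preodor_control <- function(panels, schedules, windows = window_spec(),
                            n_last = 12) {
  shift <- -(windows$baseline_s + windows$response_s)
  comp <- score_panels(panels, schedules, windows, shift_s = shift)
  discrimination_score(comp, n_last = n_last)
}

# Shared cohort scoring path: zeta transform -> trial scores -> composites.
score_panels <- function(panels, schedules, windows = window_spec(),
                         shift_s = 0) {
  if (!is.null(schedules$onset_s)) schedules <- rep(list(schedules),
                                                    length(panels))
  stopifnot(length(schedules) == length(panels))
  comp <- do.call(rbind, Map(function(panel, sched) {
    zp <- zeta_transform(panel, sched, windows, shift_s = shift_s)
    composite_scores(trial_scores(zp))
  }, panels, schedules))
  rownames(comp) <- NULL
  comp
}

#' Unpaired control with random balanced CS assignments
#'
#' For a cohort in which odors did not predict food, repeatedly assigns one
#' odor as CS+ and the other as CS- across fish in a balanced fashion, and
#' recomputes the discrimination score for each random assignment. Because
#' baseline subtraction and reference normalization are label-independent and
#' class-mean centring shifts all trials of a fish equally, relabeling the
#' trial-score table is exactly equivalent to re-running the full pipeline.
#'
#' @param comp Cohort composite-score table with an `odor` column.
#' @param n_assignments Number of random assignments (default 10).
#' @param seed RNG seed; assignments are reproducible given the seed.
#' @param n_last Trials per class entering d.
#' @return An `unpaired_control` object: one `discrimination_result` per
#'   assignment plus the assignment matrix and a summary (mean and SD of the
#'   cohort-mean d over assignments, range of p values).
#' @export
unpaired_control <- function(comp, n_assignments = 10, seed = 1,
                             n_last = 12) {
  fish <- unique(comp$fish_id)
  n <- length(fish)
  if (n %% 2 != 0) stop("cohort size must be even for balanced assignment")
  odors <- sort(unique(comp$odor))
  if (length(odors) != 2) stop("expected exactly two odors")
  set.seed(seed)
  assignments <- replicate(n_assignments,
                           sample(rep(odors, n / 2)), simplify = FALSE)
  results <- lapply(assignments, function(cs_plus) {
    names(cs_plus) <- fish
    relabeled <- comp
    relabeled$label <- ifelse(comp$odor == cs_plus[comp$fish_id],
                              "CSplus", "CSminus")
    discrimination_score(relabeled, n_last = n_last)
  })
  d <- vapply(results, function(r) r$mean_d, numeric(1))
  p <- vapply(results, function(r) r$p_signed_rank, numeric(1))
  structure(list(
    results = results,
    assignments = do.call(rbind, assignments),
    mean_d = mean(d),
    sd_d = sd(d),
    d = d,
    p = p,
    seed = seed
  ), class = "unpaired_control")
}

#' @export
print.unpaired_control <- function(x, ...) {
  cat(sprintf(
    "Unpaired control: %d random balanced assignments (seed %d)\n",
    length(x$d), x$seed))
  cat(sprintf("  d over assignments: %.3f +/- %.3f (mean +/- SD)\n",
              x$mean_d, x$sd_d))
  cat(sprintf("  signed-rank p range: %.3f - %.3f\n",
              min(x$p), max(x$p)))
  invisible(x)
}
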