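# Toy cohort score table builder: one row per trial with a given zeta_comp.
mk_scores <- function(fish_id, plus, minus, day = NULL,
                      odor_plus = "A", odor_minus = "B") {
  n <- length(plus)
  stopifnot(length(minus) == n)
  df <- data.frame(
    fish_id = fish_id,
    trial = seq_len(2 * n),
    day = if (is.null(day)) rep(1, 2 * n) else rep(day, each = 2),
    label = rep(c("CSplus", "CSminus"), n),
    odor = rep(c(odor_plus, odor_minus), n),
    zeta_comp = as.numeric(rbind(plus, minus)),
    stringsAsFactors = FALSE
  )
  df
}

test_that("the median filter matches the sliding-median oracle and trims ends", {
  expect_equal(median_filter_trials(rep(2, 7)), rep(2, 3))
  expect_equal(median_filter_trials(c(0, 0, 10, 0, 0, 0, 0)), c(0, 0, 0))
  set.seed(21)
  x <- rnorm(40)
  oracle <- vapply(3:38, function(i) median(x[(i - 2):(i + 2)]), numeric(1))
  expect_equal(median_filter_trials(x), oracle)
  expect_error(median_filter_trials(rnorm(4)), "at least 5")
  expect_error(median_filter_trials(rnorm(10), window = 4), "odd")
})

test_that("d is zero for identical classes and exactly linear in an offset", {
  set.seed(22)
  base <- rnorm(15)
  same <- mk_scores("f1", base, base)
  d0 <- discrimination_score(same, n_last = 12)
  expect_equal(unname(d0$d_per_fish), 0)
  expect_true(is.na(d0$sem_d))  # single fish: SEM undefined

  offs <- mk_scores("f1", base + 1.7, base)
  expect_equal(unname(discrimination_score(offs, n_last = 12)$d_per_fish),
               1.7, tolerance = 1e-12)

  short <- mk_scores("f1", rnorm(5), rnorm(5))
  expect_error(discrimination_score(short, n_last = 12), "fewer than 12")
})

test_that("swapping all CS labels negates the cohort mean d exactly", {
  set.seed(23)
  cohort <- do.call(rbind, lapply(1:6, function(i) {
    mk_scores(sprintf("f%d", i), rnorm(15, mean = 0.5), rnorm(15))
  }))
  d1 <- discrimination_score(cohort, n_last = 12)
  swapped <- cohort
  swapped$label <- ifelse(cohort$label == "CSplus", "CSminus", "CSplus")
  d2 <- discrimination_score(swapped, n_last = 12)
  expect_equal(d2$mean_d, -d1$mean_d, tolerance = 1e-12)
  expect_equal(d2$d_per_fish, -d1$d_per_fish, tolerance = 1e-12)
})

test_that("learning curves take per-fish daily medians before averaging", {
  # two fish, two days; identical classes give flat curves, no significance
  set.seed(24)
  base <- rnorm(18)
  cohort <- rbind(mk_scores("f1", base, base, day = rep(1:2, each = 9)),
                  mk_scores("f2", base + 1, base + 1,
                            day = rep(1:2, each = 9)))
  lc <- learning_curve(cohort)
  expect_false(any(lc$day_tests$sig05))
  cv <- lc$curve
  expect_equal(cv$mean[cv$label == "CSplus"], cv$mean[cv$label == "CSminus"],
               tolerance = 1e-12)
  # the day-1 CS+ point is the mean over fish of each fish's 9-trial median
  f1_med <- median(base[1:9])
  f2_med <- median(base[1:9] + 1)
  expect_equal(cv$mean[cv$day == 1 & cv$label == "CSplus"],
               mean(c(f1_med, f2_med)), tolerance = 1e-12)
  expect_equal(cv$n_fish, rep(2L, 4), ignore_attr = TRUE)
})

test_that("the single-trial curve median-filters per class and omits the ends", {
  set.seed(25)
  cohort <- do.call(rbind, lapply(1:8, function(i) {
    mk_scores(sprintf("f%d", i), rnorm(9, mean = 1), rnorm(9))
  }))
  tc <- trial_curve(cohort, window = 5)
  expect_equal(sort(unique(tc$class_trial)), 3:7)
  expect_true(all(c("mean", "sem", "p") %in% names(tc)))
  expect_gt(mean(tc$mean[tc$label == "CSplus"]),
            mean(tc$mean[tc$label == "CSminus"]))
})

test_that("unpaired relabeling is balanced, seeded and conservative", {
  set.seed(26)
  cohort <- do.call(rbind, lapply(1:8, function(i) {
    odor_plus <- if (i %% 2 == 0) "A" else "B"
    mk_scores(sprintf("f%d", i), rnorm(15), rnorm(15),
              odor_plus = odor_plus,
              odor_minus = setdiff(c("A", "B"), odor_plus))
  }))
  up1 <- unpaired_control(cohort, n_assignments = 10, seed = 99)
  up2 <- unpaired_control(cohort, n_assignments = 10, seed = 99)
  expect_identical(up1$assignments, up2$assignments)
  expect_identical(up1$d, up2$d)
  # every assignment is balanced
  expect_true(all(apply(up1$assignments, 1,
                        function(a) sum(a == "A") == 4)))

  odd <- cohort[cohort$fish_id != "f8", ]
  expect_error(unpaired_control(odd), "even")

  # cohort of two fish: only one distinct balanced assignment up to swap
  two <- cohort[cohort$fish_id %in% c("f1", "f2"), ]
  up3 <- unpaired_control(two, n_assignments = 5, seed = 1)
  expect_true(all(apply(up3$assignments, 1, function(a) length(unique(a)) == 2)))
})

test_that("pre-odor control windows shift reference, baseline and response together", {
  # responses locked strictly to odor onset: the shifted re-analysis must not
  # see them. Constructed panel: signal only in [onset, onset+2).
  onsets <- seq(100, by = 120, length.out = 20)
  labels <- rep(c("CSplus", "CSminus"), 10)
  set.seed(27)
  values <- rnorm(2600, sd = 0.3)
  panel <- make_panel(values, fps = 1)
  for (p in c("Speed", "Zlevel", "Area", "Surface", "Distance", "Circling"))
    panel[[p]] <- values
  for (i in which(labels == "CSplus")) {
    sel <- panel$t_s >= onsets[i] & panel$t_s < onsets[i] + 2
    for (p in c("Speed", "Zlevel", "Area", "Surface"))
      panel[[p]][sel] <- panel[[p]][sel] + 5
  }
  sched <- toy_schedule(onsets = onsets, labels = labels)
  std <- composite_scores(trial_scores(
    zeta_transform(panel, sched, toy_windows())))
  d_std <- mean(std$zeta_comp[std$label == "CSplus"]) -
    mean(std$zeta_comp[std$label == "CSminus"])
  ctrl <- preodor_control(list(panel), sched, toy_windows(), n_last = 10)
  expect_gt(d_std, 3)
  expect_lt(abs(ctrl$mean_d), d_std / 3)
})
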