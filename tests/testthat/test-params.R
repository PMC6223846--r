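geom <- tank_geometry()

test_that("speed equals displacement times frame rate", {
  static <- make_traj(rep(5, 20), rep(3, 20), rep(2, 20))
  expect_equal(compute_speed(static), rep(0, 20))

  moving <- make_traj(5 + 0.1 * (0:19), rep(3, 20), rep(2, 20))
  expect_equal(compute_speed(moving), rep(3.0, 20))

  set.seed(1)
  rnd <- make_traj(runif(200, 1, 28), runif(200, 1, 9), runif(200, 0.5, 5.5))
  oracle <- numeric(200)
  for (i in 2:200) {
    oracle[i] <- sqrt((rnd$x_cm[i] - rnd$x_cm[i - 1])^2 +
                        (rnd$y_cm[i] - rnd$y_cm[i - 1])^2 +
                        (rnd$z_cm[i] - rnd$z_cm[i - 1])^2) * 30
  }
  oracle[1] <- oracle[2]
  expect_equal(compute_speed(rnd), oracle, tolerance = 1e-12)

  # speed is never computed across a gap between contiguous runs
  gap <- rbind(make_traj(rep(1, 10)), make_traj(rep(20, 10), t0 = 100))
  attr(gap, "fps") <- 30
  class(gap) <- c("fish_trajectory", "data.frame")
  expect_equal(compute_speed(gap), rep(0, 20))

  bad <- make_traj(1:40)
  bad$t_s[5] <- bad$t_s[5] + 0.01
  expect_error(compute_speed(bad), "non-uniform")
})

test_that("z-level is the clipped relative height in the water column", {
  tr <- make_traj(rep(5, 4), rep(3, 4), c(0, 6, 4.2, 6.5))
  zl <- compute_zlevel(tr, geom)
  expect_equal(as.numeric(zl), c(0, 1, 0.7, 1))
  expect_equal(attr(zl, "n_clipped"), 1L)
})

test_that("reward-zone residence is a closed-boundary point-in-rectangle test", {
  tr <- make_traj(c(geom$ring_center[1], 28, geom$reward_zone[2], 9.7),
                  c(geom$ring_center[2], 9, 4, 4))
  expect_equal(compute_area(tr, geom), c(1, 0, 1, 0))

  set.seed(2)
  path <- make_traj(runif(500, 0, 29), runif(500, 0, 9.5))
  rz <- geom$reward_zone
  oracle <- as.numeric(path$x_cm >= rz[1] & path$x_cm <= rz[2] &
                         path$y_cm >= rz[3] & path$y_cm <= rz[4])
  expect_equal(compute_area(path, geom), oracle)
})

test_that("surface events are hysteretic upward crossings inside the ring", {
  thr <- geom$surface_threshold_frac * geom$water_height_cm  # 4.2 cm
  rc <- geom$ring_center

  # never above threshold
  low <- make_traj(rep(rc[1], 50), rep(rc[2], 50), rep(2, 50))
  expect_equal(sum(detect_surface_events(low, geom)), 0)

  # exactly three separated excursions above threshold inside the ring
  z <- rep(2, 90)
  z[11:15] <- 5; z[41:44] <- 4.5; z[71:78] <- 5.5
  three <- make_traj(rep(rc[1], 90), rep(rc[2], 90), z)
  ev <- detect_surface_events(three, geom)
  expect_equal(sum(ev), 3)
  expect_equal(which(ev == 1), c(11, 41, 71))

  # the same excursions outside the ring do not count
  far <- make_traj(rep(25, 90), rep(8, 90), z)
  expect_equal(sum(detect_surface_events(far, geom)), 0)

  # hovering at the threshold without falling below it is a single event
  z2 <- c(rep(2, 10), rep(c(4.3, 4.25), 20), rep(2, 10))
  hover <- make_traj(rep(rc[1], 60), rep(rc[2], 60), z2)
  expect_equal(sum(detect_surface_events(hover, geom)), 1)

  # run-length oracle on a random walk around the threshold
  set.seed(3)
  zr <- 4.2 + cumsum(rnorm(400, sd = 0.3))
  zr <- pmin(pmax(zr, 0.1), 5.9)
  walk <- make_traj(rep(rc[1], 400), rep(rc[2], 400), zr)
  above <- zr >= thr
  oracle_events <- sum(above & !c(FALSE, above[-400]))
  expect_equal(sum(detect_surface_events(walk, geom)), oracle_events)
})

test_that("distance to inflow is the 3D euclidean distance", {
  p <- geom$inflow_pos
  tr <- make_traj(c(p[1], p[1] + 3), c(p[2], p[2]), c(p[3], p[3]))
  expect_equal(compute_distance_to_inflow(tr, geom), c(0, 3))

  set.seed(4)
  rnd <- make_traj(runif(100, 0, 29), runif(100, 0, 9.5), runif(100, 0, 6))
  oracle <- sqrt((rnd$x_cm - p[1])^2 + (rnd$y_cm - p[2])^2 +
                   (rnd$z_cm - p[3])^2)
  expect_equal(compute_distance_to_inflow(rnd, geom), oracle,
               tolerance = 1e-12)
})

test_that("circling index separates slow rhythmic from fast or aperiodic motion", {
  n <- 120 * 30
  t <- (0:(n - 1)) / 30
  slow <- make_traj(14.5 + 10 * sin(2 * pi * 0.05 * t))
  ci_slow <- compute_circling(slow)
  interior <- seq(16 * 30, n - 16 * 30)  # bins with fully interior windows
  expect_true(all(ci_slow[interior] > 0.9))

  fast <- make_traj(14.5 + 10 * sin(2 * pi * 1.0 * t))
  expect_true(all(compute_circling(fast)[interior] < 0.05))

  flat <- make_traj(rep(14.5, n))
  expect_equal(compute_circling(flat), rep(0, n))

  # white noise: relative power ~ the band's share of non-DC periodogram bins
  set.seed(5)
  noise <- make_traj(14.5 + rnorm(n))
  ci <- compute_circling(noise)
  bins <- ci[seq(1, n, by = 30)]
  # 900-sample window, df = 1/30 Hz: 4 of 449 positive-frequency bins in band
  expected <- 4 / 449
  expect_lt(abs(mean(bins) - expected),
            4 * sd(bins) / sqrt(length(bins)) + 0.005)

  expect_error(compute_circling(make_traj(rnorm(100))), "shorter")
  expect_error(compute_circling(slow, band_hz = c(0.2, 0.1)), "increasing")
})

test_that("speed and distance are invariant to a rigid translation of the frame", {
  set.seed(6)
  tr <- make_traj(runif(80, 5, 20), runif(80, 2, 7), runif(80, 1, 5))
  shift <- c(1.5, 0.8, 0.3)
  tr2 <- tr
  tr2$x_cm <- tr$x_cm + shift[1]
  tr2$y_cm <- tr$y_cm + shift[2]
  tr2$z_cm <- tr$z_cm + shift[3]
  geom2 <- geom
  geom2$inflow_pos <- geom$inflow_pos + shift
  expect_equal(compute_speed(tr2), compute_speed(tr), tolerance = 1e-12)
  expect_equal(compute_distance_to_inflow(tr2, geom2),
               compute_distance_to_inflow(tr, geom), tolerance = 1e-12)
})

test_that("the parameter panel is frame-aligned and converts to long format", {
  sched <- assign_labels(trial_schedule(days = 1,
                                        trials_per_day_per_stimulus = 2), "A")
  traj <- simulate_fish(geom, sched, behavior_model(), seed = 12)
  panel <- compute_parameters(traj, geom)
  expect_equal(nrow(panel), nrow(traj))
  expect_true(all(panel$Zlevel >= 0 & panel$Zlevel <= 1))
  expect_true(all(panel$Area %in% c(0, 1)))
  expect_true(all(panel$Circling >= 0 & panel$Circling <= 1))
  expect_true(all(panel$Speed >= 0))
  expect_true(all(panel$Distance >= 0))
  long <- panel_long(panel)
  expect_equal(nrow(long), 6 * nrow(panel))
  expect_equal(unique(long$parameter),
               c("Speed", "Zlevel", "Area", "Surface", "Distance", "Circling"))
})
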