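PAR <- c("Speed", "Zlevel", "Area", "Surface", "Distance", "Circling")

test_that("the zeta transform reproduces the hand-computed toy oracle", {
  # 2 CS+ / 2 CS- trials; after baseline subtraction the response values are
  # {2,2,0,0} and the reference-window time-averages {1,-1,1,-1}. Worked by
  # hand: class response means {2,0}, grand centre 1, centred responses
  # {1,1,-1,-1}; sd of reference averages = 2/sqrt(3) = 1.1547; zeta_trial =
  # {1,1,-1,-1}/1.1547 = +/-0.8660254.
  panel <- toy_oracle_panel()
  zp <- zeta_transform(panel, toy_schedule(), toy_windows())
  sc <- trial_scores(zp)
  expected <- c(0.8660254, 0.8660254, -0.8660254, -0.8660254)
  expect_equal(sc$Speed, expected, tolerance = 1e-6)
  expect_equal(sc$Zlevel, expected, tolerance = 1e-6)
  # sign inversion for the "smaller is more appetitive" parameters
  expect_equal(sc$Distance, -expected, tolerance = 1e-6)
  expect_equal(sc$Circling, -expected, tolerance = 1e-6)
})

test_that("degenerate and under-specified inputs are rejected", {
  # all trials identical: zero reference variability must raise, naming the
  # parameter
  panel <- toy_oracle_panel(ref = c(1, 1, 1, 1), resp = c(2, 2, 2, 2))
  expect_error(zeta_transform(panel, toy_schedule(), toy_windows()),
               "Speed")
  # fewer than two trials per class
  expect_error(
    zeta_transform(toy_oracle_panel(), toy_schedule(
      labels = c("CSplus", "CSplus", "CSplus", "CSminus")), toy_windows()),
    "two trials")
  # missing window coverage
  sched <- toy_schedule(onsets = c(2, 30, 50, 70))
  expect_error(zeta_transform(toy_oracle_panel(), sched, toy_windows()),
               "does not cover")
})

test_that("zeta series are centred and invariant to affine rescaling", {
  set.seed(11)
  panel <- make_panel(rnorm(400), fps = 1)
  for (p in PAR) panel[[p]] <- rnorm(400, mean = 3, sd = 2)
  sched <- toy_schedule(onsets = c(20, 120, 220, 320),
                        labels = c("CSplus", "CSminus", "CSplus", "CSminus"))
  zp <- zeta_transform(panel, sched, toy_windows())

  # centering: at every time point the mean of the CS+ and CS- class-average
  # zeta equals zero to machine precision
  plus <- zp$label == "CSplus"
  for (p in PAR) {
    center <- (colMeans(zp$zeta[plus, , p]) +
                 colMeans(zp$zeta[!plus, , p])) / 2
    expect_lt(max(abs(center)), 1e-12)
  }

  # affine invariance: a*s + b leaves the zeta series unchanged (up to sign
  # convention, which is unaffected)
  panel2 <- panel
  panel2$Speed <- 3.7 * panel$Speed - 11
  panel2$Distance <- 0.25 * panel$Distance + 4
  zp2 <- zeta_transform(panel2, sched, toy_windows())
  expect_equal(zp2$zeta[, , "Speed"], zp$zeta[, , "Speed"],
               tolerance = 1e-9)
  expect_equal(zp2$zeta[, , "Distance"], zp$zeta[, , "Distance"],
               tolerance = 1e-9)

  # label swap negates every CS+ minus CS- trial-score difference
  sc <- trial_scores(zp)
  swapped <- sched
  swapped$label <- ifelse(sched$label == "CSplus", "CSminus", "CSplus")
  sc_sw <- trial_scores(zeta_transform(panel, swapped, toy_windows()))
  for (p in PAR) {
    d1 <- mean(sc[[p]][sc$label == "CSplus"]) -
      mean(sc[[p]][sc$label == "CSminus"])
    d2 <- mean(sc_sw[[p]][sc_sw$label == "CSplus"]) -
      mean(sc_sw[[p]][sc_sw$label == "CSminus"])
    expect_equal(d2, -d1, tolerance = 1e-12)
  }
})

test_that("window shifting is pure bookkeeping on the onset times", {
  set.seed(12)
  panel <- make_panel(rnorm(600), fps = 1)
  for (p in PAR) panel[[p]] <- rnorm(600)
  sched <- toy_schedule(onsets = c(100, 220, 340, 460))
  shifted_sched <- sched
  shifted_sched$onset_s <- sched$onset_s - 4
  zp_shift <- zeta_transform(panel, sched, toy_windows(), shift_s = -4)
  zp_moved <- zeta_transform(panel, shifted_sched, toy_windows())
  expect_equal(zp_shift$zeta, zp_moved$zeta, tolerance = 1e-12)
})

test_that("trial scores average the response window", {
  zp <- list(zeta = array(0, c(2, 6, 6), dimnames = list(NULL, NULL, PAR)),
             rel_t = c(-4, -3, -2, -1, 0, 1), trial = 1:2, day = c(1, 1),
             label = c("CSplus", "CSminus"), odor = c("A", "B"),
             fish_id = "f1", windows = toy_windows(),
             sign_inverted = c("Distance", "Circling"), fps = 1)
  class(zp) <- "zeta_panel"
  zp$zeta[1, , "Speed"] <- c(9, 9, 9, 9, 3, 3)     # constant over response
  zp$zeta[2, , "Speed"] <- c(0, 0, 0, 0, 0, 1)     # ramp 0 -> 1
  sc <- trial_scores(zp)
  expect_equal(sc$Speed, c(3, 0.5))
})

test_that("the Stouffer composite is sum over sqrt(6)", {
  expect_equal(stouffer_composite(rep(0, 6)), 0)
  expect_equal(stouffer_composite(rep(1, 6)), sqrt(6))
  expect_equal(stouffer_composite(c(1, -1, 1, -1, 1, -1)), 0)
  expect_equal(stouffer_composite(c(2, -1, 1, -1, 1, -1)), 1 / sqrt(6))
  expect_error(stouffer_composite(rep(1, 5)), "exactly 6")
  # linear and permutation invariant
  set.seed(13)
  v <- rnorm(6)
  expect_equal(stouffer_composite(sample(v)), stouffer_composite(v))
  expect_equal(stouffer_composite(2 * v), 2 * stouffer_composite(v))
  # matrix input, one row per trial
  m <- rbind(rep(1, 6), rep(0, 6))
  expect_equal(stouffer_composite(m), c(sqrt(6), 0))
})

test_that("covariance weighting discounts redundant parameters", {
  set.seed(14)
  scores <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(NULL, PAR))

  # identity covariance: exactly the Stouffer composite
  expect_equal(as.numeric(weighted_composite(scores, diag(6))),
               stouffer_composite(scores), tolerance = 1e-12)

  # two perfectly correlated parameters share the weight of one independent
  C <- diag(6); C[1, 2] <- C[2, 1] <- 1
  w <- attr(weighted_composite(scores, C), "weights")
  expect_equal(unname(w[1] + w[2]), unname(w[3]), tolerance = 1e-12)

  # brute-force formula on a random PSD covariance
  A <- matrix(runif(36), 6)
  C2 <- crossprod(A) + diag(6)
  got <- weighted_composite(scores, C2)
  w2 <- diag(C2) / rowSums(C2)
  expect_equal(as.numeric(got), as.numeric(scores %*% w2 / sqrt(sum(w2^2))),
               tolerance = 1e-12)
  expect_equal(unname(attr(got, "weights")), w2, tolerance = 1e-12)

  Cbad <- diag(6); Cbad[1, ] <- -1; Cbad[, 1] <- -1
  expect_error(weighted_composite(scores, Cbad), "degenerate")
})

test_that("mean trial-by-trial correlations behave at the limits and under the null", {
  mk <- function(m) {
    df <- as.data.frame(m); names(df) <- PAR
    df$fish_id <- "f"; df
  }
  # identical series in every fish: off-diagonal 1
  base <- matrix(rep(rnorm(10), 6), 10, 6)
  cc <- parameter_correlations(list(mk(base), mk(base + 1)))
  expect_equal(unname(cc[1, 2]), 1, tolerance = 1e-12)

  # anti-correlated constructed pair
  m <- base; m[, 2] <- -m[, 2]
  cc2 <- parameter_correlations(list(mk(m)))
  expect_equal(unname(cc2[1, 2]), -1, tolerance = 1e-12)

  # independent random series, 62 fish x 36 trials: mean off-diagonal ~ 0
  set.seed(15)
  cohort <- lapply(1:62, function(i) mk(matrix(rnorm(36 * 6), 36, 6)))
  cc3 <- parameter_correlations(cohort)
  off <- cc3[upper.tri(cc3)]
  expect_lt(max(abs(off)), 0.05)

  # zero-variance fish are excluded from the affected pair only
  flat <- base; flat[, 3] <- 5
  cc4 <- parameter_correlations(list(mk(base), mk(flat)))
  nf <- attr(cc4, "n_fish")
  expect_equal(nf[1, 2], 2)
  expect_equal(nf[1, 3], 1)
})
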