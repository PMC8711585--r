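test_that("split_intervals follows the floor convention and validates alpha", {
  expect_identical(split_intervals(10, 1.0),
                   c(n_nonfatigue = 10L, n_fatigue = 0L))
  expect_identical(split_intervals(7, 0.7),
                   c(n_nonfatigue = 4L, n_fatigue = 3L))
  expect_identical(split_intervals(100, 0.8),
                   c(n_nonfatigue = 80L, n_fatigue = 20L))
  expect_error(split_intervals(100, 0), class = "pitchfatigue_parameter_error")
  expect_error(split_intervals(100, 1.2),
               class = "pitchfatigue_parameter_error")
  expect_error(split_intervals(1, 0.5),
               class = "pitchfatigue_parameter_error")
})

test_that("interval_bounds reproduces hand-computed mean + SD knots", {
  # non-fatigue elbow values (100, 102, 98, 100): mean 100, sample SD
  # sqrt(8/3); fatigue values constant 120 -> zero SD
  s <- make_session(elbow = c(100, 102, 98, 100, 120, 120),
                    trunk = c(100, 100, 100, 100, 80, 80),
                    interval = c(NA, 20, 20, 20, 30, 30))
  b <- interval_bounds(s, 4 / 6)
  expect_equal(b$elbow$nf_mean, 100)
  expect_equal(b$elbow$nf_sd, sqrt(8 / 3))
  expect_equal(b$elbow$x, 100 + sqrt(8 / 3))
  expect_equal(b$elbow$y, 120)
  expect_equal(b$trunk$x, 100)  # zero variance
  expect_equal(b$interval$x, 20)
  expect_true(b$elbow$valid && b$trunk$valid && b$interval$valid)

  # population SD option
  bp <- interval_bounds(s, 4 / 6, sd = "population")
  expect_equal(bp$elbow$nf_sd, sqrt(2))

  # fewer than 2 present values in an interval
  s2 <- make_session(elbow = c(100, 100, NA, 120),
                     trunk = c(100, 100, 80, 80),
                     interval = c(10, 10, 20, 20))
  expect_error(interval_bounds(s2, 0.5),
               class = "pitchfatigue_insufficient_data")
})

test_that("interval_bounds recovers the generating statistics at large N", {
  set.seed(101)
  sim <- simulate_session(sim_config(n_pitches = 10000, n_games = 1,
                                     onset_fraction = 0.7, seed = 101))
  b <- interval_bounds(sim$session, 0.7)
  # 3-standard-error bands around the analytic mean + SD targets
  n_nf <- 7000; n_f <- 3000
  se_x <- 4 / sqrt(n_nf) * sqrt(1 + 1 / 2)  # se(mean) + se(sd) combined, crude
  expect_lt(abs(b$elbow$x - (95 + 4)), 3 * 4 / sqrt(n_nf) * 2)
  expect_lt(abs(b$elbow$y - (110 + 4)), 3 * 4 / sqrt(n_f) * 2)
  expect_lt(abs(b$trunk$x - (100 + 4)), 3 * 4 / sqrt(n_nf) * 2)
  expect_lt(abs(b$interval$y - (25 + 3)), 3 * 3 / sqrt(n_f) * 2)
})

test_that("fatigue values hit the knots, midpoints and saturation branches", {
  b <- make_bounds(x1 = 100, y1 = 110, x2 = 95, y2 = 85, x3 = 20, y3 = 30)
  expect_equal(fatigue_value_elbow(100, b), 0)
  expect_equal(fatigue_value_elbow(105, b), 0.5)
  expect_equal(fatigue_value_elbow(110, b), 1)
  expect_equal(fatigue_value_elbow(120, b), 1)
  expect_equal(fatigue_value_elbow(90, b), 0)

  expect_equal(fatigue_value_trunk(95, b), 0)
  expect_equal(fatigue_value_trunk(90, b), 0.5)
  expect_equal(fatigue_value_trunk(85, b), 1)
  expect_equal(fatigue_value_trunk(80, b), 1)
  expect_equal(fatigue_value_trunk(100, b), 0)

  expect_equal(fatigue_value_interval(20, b), 0)
  expect_equal(fatigue_value_interval(25, b), 0.5)
  expect_equal(fatigue_value_interval(31, b), 1)
  expect_equal(fatigue_value_interval(10, b), 0)
})

test_that("fatigue maps are monotone, continuous at the knots and unit-free", {
  b <- make_bounds(100, 110, 95, 85, 20, 30)
  grid_c <- seq(95, 115, by = 0.01)
  A1 <- fatigue_value_elbow(grid_c, b)
  expect_true(all(diff(A1) >= 0))           # non-decreasing in c
  expect_true(all(A1 >= 0 & A1 <= 1))
  # continuity: approach each knot from both sides
  eps <- 1e-9
  expect_lt(abs(fatigue_value_elbow(100 - eps, b) -
                  fatigue_value_elbow(100 + eps, b)), 1e-6)
  expect_lt(abs(fatigue_value_elbow(110 - eps, b) -
                  fatigue_value_elbow(110 + eps, b)), 1e-6)
  A2 <- fatigue_value_trunk(seq(80, 100, by = 0.01), b)
  expect_true(all(diff(A2) <= 0))           # non-increasing in k

  # affine invariance: rescale value and knots together
  for (rep in 1:20) {
    a <- stats::runif(1, 0.1, 10); d <- stats::runif(1, -50, 50)
    v <- stats::runif(1, 90, 120)
    b2 <- make_bounds(a * 100 + d, a * 110 + d, 95, 85, 20, 30)
    expect_equal(fatigue_value_elbow(a * v + d, b2),
                 fatigue_value_elbow(v, b), tolerance = 1e-9)
  }
})

test_that("degenerate bounds error by default and step when configured", {
  b <- make_bounds(x1 = 110, y1 = 100, x2 = 85, y2 = 95, x3 = 30, y3 = 20)
  expect_error(fatigue_value_elbow(105, b),
               class = "pitchfatigue_degenerate_bounds")
  expect_error(fatigue_value_trunk(90, b),
               class = "pitchfatigue_degenerate_bounds")
  expect_error(fatigue_value_interval(25, b),
               class = "pitchfatigue_degenerate_bounds")
  # step fallback: past x toward fatigue -> 1, else 0
  expect_equal(fatigue_value_elbow(c(115, 110, 105), b, "step"),
               c(1, 0, 0))
  expect_equal(fatigue_value_trunk(c(80, 85, 90), b, "step"), c(1, 0, 0))
  expect_equal(fatigue_value_interval(c(35, 30, 25), b, "step"),
               c(1, 0, 0))

  # identically distributed intervals make x ~ y: the error path fires
  set.seed(33)
  s <- make_session(elbow = rep(c(100, 102), 20),
                    trunk = rep(c(90, 92), 20),
                    interval = rep(c(20, 21), 20))
  bs <- interval_bounds(s, 0.5)
  expect_false(bs$elbow$valid)
  expect_error(score_session(s, bs),
               class = "pitchfatigue_degenerate_bounds")
})

test_that("score_session propagates missing features and stays in [0, 1]", {
  b <- make_bounds(100, 110, 95, 85, 20, 30)
  s <- make_session(elbow = c(105, 102), trunk = c(90, 93),
                    interval = c(NA, 25))
  sc <- score_session(s, b)
  expect_true(is.na(sc$A3[1]))
  expect_false(anyNA(sc[1, c("A1", "A2")]))
  expect_equal(sc$A3[2], 0.5)

  set.seed(34)
  sim <- simulate_session(sim_config(n_pitches = 500, n_games = 1,
                                     missing_rate = 0.2, seed = 34))
  bb <- interval_bounds(sim$session, 0.7)
  ss <- score_session(sim$session, bb)
  vals <- unlist(ss[, c("A1", "A2", "A3")])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
  # exactly the missing features give missing scores
  expect_identical(is.na(ss$A1), is.na(sim$session$features$elbow_angle_deg))
  expect_identical(is.na(ss$A3), is.na(sim$session$features$interval_s))
})

test_that("bounds persist to JSON and back", {
  set.seed(35)
  sim <- simulate_session(sim_config(n_pitches = 100, n_games = 1, seed = 35))
  b <- interval_bounds(sim$session, 0.7)
  path <- withr::local_tempfile(fileext = ".json")
  write_bounds(b, path)
  b2 <- read_bounds(path)
  expect_equal(b2$elbow, b$elbow)
  expect_equal(b2$trunk, b$trunk)
  expect_equal(b2$interval, b$interval)
  expect_equal(b2$alpha, b$alpha)
  # scoring through restored bounds is identical
  expect_equal(score_session(sim$session, b2),
               score_session(sim$session, b))
})

test_that("symmetric bounds flip the trunk knots to mean - SD", {
  s <- make_session(elbow = c(100, 102, 98, 100, 120, 121),
                    trunk = c(100, 102, 98, 100, 85, 86),
                    interval = c(NA, 20, 21, 20, 30, 31))
  b <- interval_bounds(s, 4 / 6, symmetric_bounds = TRUE)
  expect_equal(b$trunk$x, 100 - sqrt(8 / 3))
  expect_equal(b$elbow$x, 100 + sqrt(8 / 3))  # up-shifting features unchanged
})
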