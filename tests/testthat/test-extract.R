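make_recording <- function(torque, displacement = NULL, fs = 1000,
                           stim = 101L) {
  n <- length(torque)
  if (is.null(displacement)) displacement <- numeric(n)
  trig <- numeric(n)
  trig[stim] <- 1
  twitch_recording(torque, displacement, trig, fs, stim)
}

test_that("torque calibration scales elementwise", {
  expect_equal(calibrate_torque(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(calibrate_torque(rep(2, 5), 50), rep(100, 5))
  set.seed(8)
  v <- rnorm(200)
  f <- runif(1, 0.5, 100)
  expect_equal(calibrate_torque(v, f), v * f, tolerance = 1e-15)
  expect_error(calibrate_torque(v, 0), class = "tmg_invalid_calibration")
  expect_error(calibrate_torque(v, -2), class = "tmg_invalid_calibration")
})

test_that("trigger detection finds rising edges only", {
  expect_identical(detect_triggers(rep(0, 100), 0.5), integer(0))
  tr <- numeric(1000); tr[500] <- 1
  expect_identical(detect_triggers(tr, 0.5), 500L)
  tr2 <- numeric(20001); tr2[5000] <- 1; tr2[15000] <- 1
  idx <- detect_triggers(tr2, 0.5)
  expect_identical(idx, c(5000L, 15000L))
  expect_equal(diff(idx), 10000)
  # a plateau is one edge; a trace starting high has no rising edge
  tr3 <- c(1, 1, 0, 1, 1)
  expect_identical(detect_triggers(tr3, 0.5), 4L)
})

test_that("rolling-median MVIC resists spikes and respects the floor", {
  expect_equal(extract_mvic(rep(100, 1000)), 100)
  x <- rep(100, 1200); x[600] <- 500
  expect_equal(extract_mvic(x), 100)
  expect_true(is.na(extract_mvic(rep(10, 1000))))
  expect_error(extract_mvic(rep(100, 400), window = 501),
               class = "tmg_invalid_config")
  expect_error(extract_mvic(rep(100, 1000), window = 500),
               class = "tmg_invalid_config")
})

test_that("rolling-median MVIC equals the exhaustive window oracle", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(200:900, 1)
    w <- sample(seq(21, 101, by = 2), 1)
    x <- 25 + cumsum(rnorm(n)) + rnorm(n, sd = 4)
    expect_equal(extract_mvic(x, window = w, floor = 20),
                 oracle_mvic(x, w, floor = 20), tolerance = 1e-12)
  }
  # one full-size case at the default window
  set.seed(15)
  x <- 60 + cumsum(rnorm(5000, sd = 0.2))
  expect_equal(extract_mvic(x, 501, 20), oracle_mvic(x, 501, 20),
               tolerance = 1e-12)
})

test_that("twitch peak torque is baseline-invariant and recovers amplitude", {
  rec0 <- make_recording(numeric(600))
  expect_equal(twitch_peak_torque(rec0), 0)

  sh <- twitch_shape(20, 25, 120, onset_delay = 10)
  t_ms <- (seq_len(600) - 101) * 1
  tq <- tmgtwitch:::eval_twitch(sh, t_ms)
  rec <- make_recording(tq)
  # cutoff far above the twitch bandwidth: peak passes almost unattenuated
  pt <- twitch_peak_torque(rec, cutoff = 200)
  expect_equal(pt, 20, tolerance = 0.02 * 20)

  rec_off <- make_recording(tq + 5)
  expect_equal(twitch_peak_torque(rec_off, cutoff = 200), pt,
               tolerance = 1e-9)

  expect_error(twitch_peak_torque(make_recording(numeric(200)),
                                  analysis_window_ms = 300),
               class = "tmg_invalid_config")
})

test_that("displacement parameters are exact on a piecewise-linear ramp", {
  fs <- 1000
  n <- 600
  stim <- 101L
  x <- numeric(n)
  ramp <- seq_len(100)                       # 0 -> 10 mm over 100 ms
  x[stim + ramp] <- ramp / 100 * 10
  x[(stim + 101):n] <- 10
  rec <- make_recording(numeric(n), displacement = x, stim = stim)
  dp <- displacement_params(rec)
  expect_equal(dp$Dm, 10)
  expect_equal(dp$Td, 10)
  expect_equal(dp$Tc, 80)
  expect_false(dp$no_displacement)
})

test_that("all-zero displacement raises the no-displacement flag", {
  rec <- make_recording(numeric(500))
  dp <- displacement_params(rec)
  expect_true(dp$no_displacement)
  expect_true(is.na(dp$Dm) && is.na(dp$Td) && is.na(dp$Tc))
})

test_that("sampled displacement parameters match an oversampled oracle", {
  set.seed(21)
  for (i in 1:10) {
    dm <- runif(1, 1, 10)
    td <- runif(1, 5, 35)
    tc <- runif(1, 15, 40)
    sh <- tmgtwitch:::shape_for_timing(dm, td, tc)
    t_ms <- (seq_len(600) - 101)
    disp <- tmgtwitch:::eval_twitch(sh, t_ms)
    rec <- make_recording(numeric(600), displacement = disp)
    dp <- displacement_params(rec)
    ref <- oracle_displacement(sh)
    expect_equal(dp$Dm, unname(ref["Dm"]), tolerance = 0.01)
    expect_lt(abs(dp$Td - ref["Td"]), 0.5)
    expect_lt(abs(dp$Tc - ref["Tc"]), max(0.5, 0.01 * ref["Tc"]))
  }
})

test_that("displacement parameters are invariant to a uniform time shift", {
  sh <- tmgtwitch:::shape_for_timing(5, 15, 25)
  fs <- 1000
  mk <- function(stim) {
    n <- 700L
    t_ms <- (seq_len(n) - stim)
    disp <- tmgtwitch:::eval_twitch(sh, t_ms)
    make_recording(numeric(n), displacement = disp, stim = as.integer(stim))
  }
  d1 <- displacement_params(mk(101))
  d2 <- displacement_params(mk(151))
  expect_equal(d1$Dm, d2$Dm, tolerance = 1e-9)
  expect_equal(d1$Td, d2$Td, tolerance = 1e-9)
  expect_equal(d1$Tc, d2$Tc, tolerance = 1e-9)
})

test_that("scaling displacement scales Dm and leaves timing unchanged", {
  sh <- tmgtwitch:::shape_for_timing(4, 18, 22)
  t_ms <- (seq_len(600) - 101)
  disp <- tmgtwitch:::eval_twitch(sh, t_ms)
  d1 <- displacement_params(make_recording(numeric(600), disp))
  d3 <- displacement_params(make_recording(numeric(600), 3 * disp))
  expect_equal(d3$Dm, 3 * d1$Dm, tolerance = 1e-9)
  expect_equal(d3$Td, d1$Td, tolerance = 1e-9)
  expect_equal(d3$Tc, d1$Tc, tolerance = 1e-9)
})
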