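fs <- 80

test_that("zero-phase Butterworth filter matches closed-form two-pass gains", {
  t <- seq(0, 10, by = 1 / fs)
  # |H|^2 of an order-2 Butterworth: 1 / (1 + (f/fc)^4)
  for (f in c(0.5, 1, 2)) {
    y <- butter_filter(sin(2 * pi * f * t), fs, cutoff_hz = 2, type = "low")
    expect_equal(
      max(abs(y[200:600])), 1 / (1 + (f / 2)^4),
      tolerance = 2e-3
    )
  }
  # deeper in the stop band the bilinear transform deviates slightly from
  # the analog prototype
  y4 <- butter_filter(sin(2 * pi * 4 * t), fs, 2, "low")
  expect_equal(max(abs(y4[200:600])), 1 / (1 + 2^4), tolerance = 0.05)
  # DC gain exactly 1 (low-pass) and 0 (high-pass)
  dc <- butter_filter(rep(5, 400), fs, 2, "low")
  expect_equal(dc[10:390], rep(5, 381), tolerance = 1e-9)
  hp <- butter_filter(rep(5, 400), fs, 0.75, "high")
  expect_lt(max(abs(hp[10:390])), 1e-9)
})

test_that("filtering is linear and zero-lag", {
  set.seed(1)
  x <- rnorm(500)
  y <- rnorm(500)
  lhs <- butter_filter(2 * x + 3 * y, fs, 2, "low")
  rhs <- 2 * butter_filter(x, fs, 2, "low") + 3 * butter_filter(y, fs, 2, "low")
  expect_equal(lhs, rhs, tolerance = 1e-9)

  # cross-correlation peak of a band-limited input with its output is lag 0
  t <- seq(0, 10, by = 1 / fs)
  s <- sin(2 * pi * 0.8 * t) + 0.5 * sin(2 * pi * 1.5 * t)
  out <- butter_filter(s, fs, 2, "low")
  cc <- stats::ccf(out, s, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("too-short signals are rejected with the minimum length", {
  expect_error(butter_filter(rnorm(8), fs, 2, "low"), "minimum")
})

test_that("trapezoidal integration matches closed forms", {
  expect_equal(tail(integrate_angular(rep(10, 161), fs), 1), 20)
  t <- seq(0, 3, by = 1 / fs)
  a <- 3
  f <- 1
  omega <- 2 * pi * f * a * cos(2 * pi * f * t)
  theta <- integrate_angular(omega, fs)
  expect_lt(max(abs(theta - a * sin(2 * pi * f * t))), 0.02)
  expect_equal(integrate_angular(rep(0, 100), fs), rep(0, 100))
})

test_that("integration then differentiation recovers band-limited signals", {
  t <- seq(0, 10, by = 1 / fs)
  s <- butter_filter(sin(2 * pi * 0.9 * t) + 0.4 * sin(2 * pi * 1.7 * t), fs, 2, "low")
  theta <- integrate_angular(s, fs)
  ds <- c(diff(theta) * fs, NA)
  # central estimate: compare midpoints (trapezoid differentiates to midpoint)
  mid <- (s[-1] + s[-length(s)]) / 2
  err <- sqrt(mean((ds[-length(ds)] - mid)^2))
  expect_lt(err / sd(s), 0.01)
})

test_that("per-cycle integration restarts at zero and bounds drift", {
  p <- clean_params()
  p$drift_dps <- 1
  tr <- generate_trial(p)
  w <- butter_filter(tr$streams$T6$gyro_z_dps, fs, 2, "low")
  t <- tr$streams$T6$time_s
  ev <- tr$truth$events
  segs <- per_cycle_displacement(w - mean(w[t >= ev$heel_strikes[1] &
    t <= ev$heel_strikes[9]]), t, ev, fs)
  expect_equal(nrow(segs), 8)
  expect_true(all(vapply(segs$theta, function(th) th[1] == 0, logical(1))))
  roms <- vapply(segs$theta, rom, numeric(1))
  expect_true(all(abs(roms - 5.6) / 5.6 < 0.05))
  # trial-level unrestarted integration without bias handling drifts away
  theta_trial <- integrate_angular(w, fs)
  expect_gt(abs(theta_trial[length(theta_trial)]), 5)
})

test_that("single heel-strike yields no cycles", {
  segs <- per_cycle_displacement(
    rnorm(400), (0:399) / fs,
    list(heel_strikes = 1.0), fs
  )
  expect_equal(nrow(segs), 0)
})

test_that("time normalization preserves endpoints and linearity", {
  y <- seq(0, 1, length.out = 80)
  z <- time_normalize(y)
  expect_length(z, 101)
  expect_equal(z[c(1, 101)], c(0, 1))
  expect_equal(z, seq(0, 1, length.out = 101), tolerance = 1e-9)
  # sinusoid resampling error well below 0.5% of amplitude
  u <- seq(0, 1, length.out = 88)
  s <- sin(2 * pi * u)
  sr <- time_normalize(s, 101)
  ref <- sin(2 * pi * seq(0, 1, length.out = 101))
  expect_lt(sqrt(mean((sr - ref)^2)), 0.005)
})

test_that("trial-level high-passed displacement suppresses drift", {
  t <- seq(0, 20, by = 1 / fs)
  omega <- 10 * cos(2 * pi * 1.5 * t) + 0.5 # 0.5 deg/s bias
  th <- trial_displacement_highpassed(omega, fs)
  # without the high-pass the ramp reaches ~10 deg; with it, bounded
  expect_lt(max(abs(th[t > 2 & t < 18])), 2.5)
})
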