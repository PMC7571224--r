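u <- seq(0, 1, length.out = 88)

test_that("ROM is the peak-to-peak range and is shift/scale consistent", {
  theta <- 3 * sin(2 * pi * u)
  expect_equal(rom(theta), 6, tolerance = 1e-2)
  expect_equal(rom(rep(2.5, 50)), 0)
  expect_equal(rom(theta + 100), rom(theta)) # shift invariance
  expect_equal(rom(5 * theta), 5 * rom(theta)) # amplitude linearity
})

test_that("phase angle traverses 360 degrees on a circular portrait", {
  theta <- sin(2 * pi * u)
  omega <- cos(2 * pi * u)
  ph <- phase_angle(omega, theta)
  d <- diff(ph)
  d[d > 180] <- d[d > 180] - 360 # unwrap the single branch jump
  expect_true(all(d < 0)) # monotone traversal
  expect_equal(abs(sum(d)), 360, tolerance = 2)
  # normalization invariance
  expect_equal(phase_angle(10 * omega, 10 * theta), ph)
  # quarter-turn shifted trajectory
  ph2 <- phase_angle(-sin(2 * pi * u), cos(2 * pi * u))
  dd <- ((ph2 - ph + 180) %% 360) - 180
  expect_equal(abs(mean(dd)), 90, tolerance = 2)
})

test_that("zero-amplitude cycles flag phase as undefined", {
  expect_null(phase_angle(rep(0, 50), rep(1, 50)))
  out <- mean_relative_phase(
    rep(0, 50), rep(0, 50), cos(2 * pi * u[1:50]), sin(2 * pi * u[1:50])
  )
  expect_null(out)
})

test_that("mean relative phase recovers imposed lags and respects invariances", {
  mk <- function(lag_deg, amp = 1) {
    list(
      theta = amp * sin(2 * pi * u - lag_deg * pi / 180),
      omega = amp * cos(2 * pi * u - lag_deg * pi / 180)
    )
  }
  t6 <- mk(0)
  for (lag in c(0, 30, 60, 90, 120, 150, 180)) {
    s1 <- mk(lag)
    out <- mean_relative_phase(t6$omega, t6$theta, s1$omega, s1$theta)
    expect_equal(out$mrp_deg, lag, tolerance = 1)
    expect_gte(out$mrp_deg, 0)
    expect_lte(out$mrp_deg, 180)
  }
  # identical waveforms -> 0; half-cycle shift -> 180
  same <- mean_relative_phase(t6$omega, t6$theta, t6$omega, t6$theta)
  expect_equal(same$mrp_deg, 0)
  anti <- mk(180)
  expect_equal(
    mean_relative_phase(t6$omega, t6$theta, anti$omega, anti$theta)$mrp_deg,
    180,
    tolerance = 1
  )
  # amplitude rescaling of either site leaves the result unchanged
  s1 <- mk(110)
  big <- mk(110, amp = 20)
  expect_equal(
    mean_relative_phase(t6$omega, t6$theta, s1$omega, s1$theta)$mrp_deg,
    mean_relative_phase(t6$omega, t6$theta, big$omega, big$theta)$mrp_deg
  )
  # common time shift of both sites cancels
  sh <- 17
  t6s <- list(
    theta = sin(2 * pi * (u - sh / 88)), omega = cos(2 * pi * (u - sh / 88))
  )
  s1s <- list(
    theta = sin(2 * pi * (u - sh / 88) - 110 * pi / 180),
    omega = cos(2 * pi * (u - sh / 88) - 110 * pi / 180)
  )
  expect_equal(
    mean_relative_phase(t6s$omega, t6s$theta, s1s$omega, s1s$theta)$mrp_deg,
    110,
    tolerance = 1.5
  )
})

test_that("full-pipeline lag recovery is within 2 degrees across the range", {
  anthro <- default_anthro()
  for (lag in c(0, 60, 120, 180)) {
    p <- clean_params(
      phase_lag_deg = c(coronal = lag, transverse = lag, sagittal = lag)
    )
    ft <- process_trial(generate_trial(p)$streams, anthro)
    expect_lt(abs(mean(ft$mrp_coronal) - lag), 2)
    expect_lt(abs(mean(ft$mrp_transverse) - lag), 2)
    expect_lt(abs(mean(ft$mrp_sagittal) - lag), 2)
  }
})

test_that("ensemble curves average cycles within participants first", {
  # participant A: 2 identical cycles at 100 deg; participant B: 4 at 40 deg.
  # participant-first averaging gives (100+40)/2 = 70; naive pooling of the
  # six cycles would give (2*100+4*40)/6 = 60.
  rp_a <- lapply(1:2, function(i) rep(100, 50))
  rp_b <- lapply(1:4, function(i) rep(40, 50))
  cycles <- tibble::tibble(
    participant = c("A", "A", "B", "B", "B", "B"),
    rp = c(rp_a, rp_b)
  )
  pc <- ensemble_phase_curve(cycles, condition = "test")
  expect_equal(unique(pc$mean_deg), 70)
  expect_equal(nrow(pc), 101)
  expect_equal(range(pc$pct), c(0, 100))
  # two participant means 100 and 40: SE = sd(c(100, 40)) / sqrt(2) = 30
  expect_equal(unique(pc$se_deg), 30, tolerance = 1e-9)
})

test_that("ensemble curves separate two conditions by their lag difference", {
  anthro <- default_anthro()
  curves <- lapply(c(60, 120), function(lag) {
    p <- clean_params(
      phase_lag_deg = c(coronal = lag, transverse = 102, sagittal = 82)
    )
    ft <- process_trial(generate_trial(p)$streams, anthro, keep_rp = TRUE)
    ft$participant <- "P01"
    suppressWarnings(ensemble_phase_curve(
      dplyr::select(ft, "participant", rp = "rp_coronal"),
      condition = paste0("lag", lag)
    ))
  })
  gap <- curves[[2]]$mean_deg - curves[[1]]$mean_deg
  expect_true(all(abs(gap - 60) < 3))
})

test_that("phase-curve and EMM autoplots build without error", {
  pc <- tibble::tibble(
    pct = seq(0, 100), mean_deg = 100 + sin(seq(0, 100) / 8),
    se_deg = 3, n_participants = 9, condition = "NL"
  )
  class(pc) <- c("gait_phase_curve", class(pc))
  expect_s3_class(autoplot(pc), "ggplot")
})
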