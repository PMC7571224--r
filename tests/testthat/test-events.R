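test_that("all heel-strikes of a noisy trial are detected accurately", {
  p <- gait_sim_params(n_cycles = 10, noise_sd_dps = 5, seed = 7)
  tr <- generate_trial(p)
  w <- butter_filter(tr$streams$shank_R$gyro_y_dps, 80, 2, "low")
  ev <- detect_gait_events(w, 80, t = tr$streams$shank_R$time_s)
  expect_equal(length(ev$heel_strikes), 11)
  expect_equal(length(ev$toe_offs), 10)
  err <- ev$heel_strikes - tr$truth$events$heel_strikes
  expect_lte(median(abs(err)), 0.025) # 25 ms
  # exactly one toe-off and one mid-swing peak per cycle, ordered
  expect_true(all(ev$toe_offs > ev$heel_strikes[1:10] &
    ev$toe_offs < ev$heel_strikes[2:11]))
  expect_true(all(ev$toe_offs < ev$mid_swing_peaks[2:11]))
})

test_that("degenerate signals raise 'no gait detected'", {
  expect_error(detect_gait_events(rep(0, 400), 80), "no gait detected")
  expect_error(detect_gait_events(rnorm(100), 80), "at least 2 s")
})

test_that("polarity auto-flip recovers from inverted mounting", {
  tw <- trial_with_events()
  ev_flipped <- detect_gait_events(-tw$shank_filtered, tw$fs,
    t = tw$trial$streams$shank_R$time_s
  )
  expect_true(ev_flipped$flipped)
  expect_equal(ev_flipped$heel_strikes, tw$events$heel_strikes)
})

test_that("detection error shrinks as noise vanishes", {
  med_err <- vapply(c(20, 5, 0), function(ns) {
    p <- gait_sim_params(n_cycles = 8, noise_sd_dps = ns, seed = 21)
    tr <- generate_trial(p)
    w <- butter_filter(tr$streams$shank_R$gyro_y_dps, 80, 2, "low")
    ev <- detect_gait_events(w, 80, t = tr$streams$shank_R$time_s)
    k <- min(length(ev$heel_strikes), 9)
    median(abs(ev$heel_strikes[1:k] - tr$truth$events$heel_strikes[1:k]))
  }, numeric(1))
  expect_lte(med_err[3], med_err[1] + 0.005)
  expect_lte(med_err[3], 1 / 80) # at noise 0, within one sample
})

test_that("cycle-selection policy picks cycles 2-6 and validates counts", {
  ev8 <- list(heel_strikes = 0:7 * 1.1) # 7 cycles
  expect_equal(segment_cycles(ev8, keep = 5), 2:6)
  ev6 <- list(heel_strikes = 0:5 * 1.1) # 5 cycles
  expect_error(segment_cycles(ev6, keep = 5), "insufficient cycles")
  ev12 <- list(heel_strikes = 0:11 * 1.1) # 11 cycles
  expect_equal(segment_cycles(ev12, keep = "all"), 2:11)
})

test_that("stride geometry is exact for zero rotation and homogeneous in lengths", {
  tw <- trial_with_events()
  t <- tw$trial$streams$shank_R$time_s
  zero <- rep(0, length(t))
  sl0 <- stride_lengths(zero, zero, t, tw$events,
    thigh_length_m = 0.5, shank_length_m = 0.44, fs = tw$fs
  )
  expect_true(all(sl0$stride_length_m == 0))

  thigh <- tw$trial$streams$thigh_R$gyro_y_dps
  shank <- tw$trial$streams$shank_R$gyro_y_dps
  s1 <- stride_lengths(thigh, shank, t, tw$events,
    thigh_length_m = 0.5, shank_length_m = 0.44, fs = tw$fs
  )
  s2 <- stride_lengths(thigh, shank, t, tw$events,
    thigh_length_m = 1.0, shank_length_m = 0.88, fs = tw$fs
  )
  ok <- !is.na(s1$stride_length_m)
  expect_equal(s2$stride_length_m[ok], 2 * s1$stride_length_m[ok],
    tolerance = 1e-9
  )
  # missing thigh stream: stride absent, temporal parameters retained
  s3 <- stride_lengths(NULL, shank, t, tw$events,
    thigh_length_m = 0.5, shank_length_m = 0.44, fs = tw$fs
  )
  expect_true(all(is.na(s3$stride_length_m)))
})

test_that("stride estimates recover a known target within 10%", {
  p <- clean_params(stride_length_m = 1.40)
  tr <- generate_trial(p)
  anthro <- default_anthro()
  ft <- process_trial(tr$streams, anthro, keep = "all")
  expect_lt(abs(mean(ft$stride_length_m) - 1.40) / 1.40, 0.10)
})

test_that("relative speed follows its definition and centers to zero", {
  expect_equal(relative_speed(1.40, 1.28, 0.94), 1.164, tolerance = 5e-4)
  expect_error(relative_speed(1.4, 1.28, 0), "positive")
  f <- tibble::tibble(relative_speed = runif(50, 0.9, 1.3))
  expect_lt(abs(sum(center_relative_speed(f)$centered_relative_speed)), 1e-9)
})

test_that("relative speed of the first design preset matches its target", {
  d <- generate_design("expt1", master_seed = 9, n_participants = 4)
  f <- process_design(d)
  # preset draws participant relative speeds around 1.09
  expect_lt(abs(mean(f$relative_speed, na.rm = TRUE) - 1.09), 0.08)
  # estimated relative speed tracks per-cycle ground truth closely
  tj <- dplyr::inner_join(
    dplyr::mutate(f,
      carry_mode = as.character(carry_mode), load = as.character(load)
    ),
    dplyr::mutate(d$truth_cycles,
      carry_mode = as.character(carry_mode), load = as.character(load)
    ),
    by = c("participant", "carry_mode", "load", "trial", "cycle"),
    suffix = c("", "_true")
  )
  expect_lt(
    abs(mean(tj$relative_speed - tj$rel_speed, na.rm = TRUE)), 0.02
  )
})
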