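test_that("same seed reproduces a trial exactly", {
  p <- fast_params()
  a <- generate_trial(p)
  b <- generate_trial(p)
  expect_identical(a$streams$T6$gyro_z_dps, b$streams$T6$gyro_z_dps)
  expect_identical(a$streams$shank_R$gyro_y_dps, b$streams$shank_R$gyro_y_dps)
  expect_identical(a$truth$cycles, b$truth$cycles)
})

test_that("ground-truth events satisfy their invariants", {
  tr <- generate_trial(fast_params())
  ev <- tr$truth$events
  expect_length(ev$heel_strikes, 9) # n_cycles + 1
  expect_length(ev$toe_offs, 8) # n_cycles
  expect_true(all(diff(ev$heel_strikes) > 0))
  # each toe-off strictly between consecutive heel-strikes
  expect_true(all(ev$toe_offs > ev$heel_strikes[1:8] &
    ev$toe_offs < ev$heel_strikes[2:9]))
})

test_that("zero lag and zero noise make T6 and S1 proportional", {
  p <- clean_params(
    phase_lag_deg = c(coronal = 0, transverse = 0, sagittal = 0)
  )
  tr <- generate_trial(p)
  z6 <- tr$streams$T6$gyro_z_dps
  z1 <- tr$streams$S1$gyro_z_dps
  ratio <- 3.75 / 2.8 # S1 vs T6 coronal amplitude
  expect_lt(max(abs(z1 - ratio * z6)), 1e-9)
})

test_that("emitted angular velocity is the exact derivative of displacement", {
  tr <- generate_trial(clean_params())
  th <- integrate_angular(tr$streams$T6$gyro_z_dps, 80)
  # integrating back recovers a sinusoid of the configured amplitude
  expect_lt(abs(diff(range(th)) - 5.6), 0.1)
  # per-cycle peak-to-peak equals 2 x amplitude exactly (conservation)
  ev <- tr$truth$events
  t <- tr$streams$T6$time_s
  for (i in c(1, 4, 8)) {
    idx <- t >= ev$heel_strikes[i] & t <= ev$heel_strikes[i + 1]
    expect_equal(diff(range(th[idx])), 5.6, tolerance = 5e-3)
  }
})

test_that("condition effects shift amplitudes and lags as configured", {
  p <- clean_params()
  eff <- preset_table3()
  side_h <- generate_trial(p, eff, list(carry_mode = "side", load = "H"))
  ant_h <- generate_trial(p, eff, list(carry_mode = "anterior", load = "H"))
  expect_equal(side_h$truth$phase_lag_deg[["coronal"]], 109.5 + 23.6)
  expect_equal(ant_h$truth$phase_lag_deg[["coronal"]], 109.5 - 30.2)
  # T6 coronal ROM truth drops by 1.8 deg at high load
  rom_h <- dplyr::filter(
    side_h$truth$rom, .data$site == "T6", .data$plane == "coronal"
  )$rom_deg[1]
  expect_equal(rom_h, 5.6 - 1.8, tolerance = 0.01)
  # no-load cells carry no offsets under either mode label
  nl <- generate_trial(p, eff, list(carry_mode = "side", load = "NL"))
  expect_equal(nl$truth$phase_lag_deg[["coronal"]], 109.5)
})

test_that("design presets produce the right bookkeeping", {
  d <- generate_design("expt1", master_seed = 5, n_participants = 2)
  expect_equal(nrow(d$manifest), 32) # 2 x 8 x 2
  expect_equal(nrow(d$truth_cycles), 32 * 8)
  expect_equal(d$keep, 5)
  expect_error(
    generate_design("expt1", n_cycles = 6),
    "at least 7"
  )
  d2 <- generate_design("expt2", master_seed = 5, n_participants = 2)
  expect_equal(nrow(d2$manifest), 16)
  expect_equal(nrow(d2$drop_list), 3)
  expect_true(all(d2$drop_list$cycle == 6))
})

test_that("written designs round-trip through their files", {
  dir <- withr::local_tempdir()
  d <- generate_design("expt1",
    master_seed = 3, n_participants = 1, dir = dir
  )
  expect_equal(nrow(d$manifest), 16)
  expect_length(list.files(dir, pattern = "_t6\\.csv$"), 16)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 16)
  s <- read_sensor_stream(m$shank_r_file[1], "shank_R")
  expect_gt(nrow(s), 500)
})

test_that("pendulum fixture obeys the small-angle closed form", {
  p1 <- generate_pendulum(initial_deg = 5)
  p2 <- generate_pendulum(arm_length_m = 2 * 0.46, initial_deg = 5)
  # doubling the arm scales the period by sqrt(2)
  expect_equal(p2$period_s / p1$period_s, sqrt(2), tolerance = 1e-9)
  # measured zero-crossing period close to 2*pi*sqrt(2L/3g) at small angle
  zc <- which(diff(sign(p1$theta_deg)) < 0)
  measured <- mean(diff(p1$t[zc]))
  expect_equal(measured, p1$period_s, tolerance = 0.01)
  # zero initial displacement gives an all-zero signal
  p0 <- generate_pendulum(initial_deg = 0)
  expect_lt(max(abs(p0$omega_dps)), 1e-8)
})

test_that("integration pipeline reproduces pendulum displacement within 1 degree", {
  pend <- generate_pendulum() # 75 deg start, 30 s, noise-free
  expect_lt(pendulum_pipeline_rmse(pend), 1)
})
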