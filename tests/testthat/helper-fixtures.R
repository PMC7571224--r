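# Shared fixtures for the test suite. Everything is generated in code; the
# sizes are kept small so the default run stays fast.

fast_params <- function(...) {
  gait_sim_params(n_cycles = 8, seed = 11, ...)
}

clean_params <- function(...) {
  gait_sim_params(noise_sd_dps = 0, drift_dps = 0, n_cycles = 8, seed = 11, ...)
}

# one filtered trial with detected events, cached per session
trial_with_events <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- generate_trial(fast_params())
      fs <- 80
      w <- butter_filter(tr$streams$shank_R$gyro_y_dps, fs, 2, "low")
      ev <- detect_gait_events(w, fs, t = tr$streams$shank_R$time_s)
      cache <<- list(trial = tr, events = ev, shank_filtered = w, fs = fs)
    }
    cache
  }
})

default_anthro <- function(leg = 0.94) {
  tibble::tibble(
    participant = "P01", stature_m = 1.76, leg_length_m = leg,
    thigh_length_m = 0.53 * leg, shank_length_m = 0.47 * leg
  )
}
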