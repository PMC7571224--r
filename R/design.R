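# Study-design presets for the synthetic generator.
#
# expt1: 9 participants x (2 modes x 4 loads) x 2 trials, 8 complete cycles
#        per trial, cycles 2-6 analyzed -> 144 trials, 720 analyzed cycles.
# expt2: 10 participants x 8 conditions x 1 longer trial, 12 complete
#        cycles, cycles 2-11 analyzed, with the 6th cycle of three
#        designated trials discarded -> 80 trials, 797 analyzed cycles.
# The empty-handed reference is generated under both mode labels with zero
# condition effects, completing the crossed bookkeeping of both designs.

design_spec <- function(design) {
  switch(design,
    expt1 = list(
      n_participants = 9, n_trials = 2, n_cycles = 8,
      keep = 5, min_cycles = 7,
      stature = c(1.76, 0.06), leg = c(0.94, 0.06),
      rel_speed = c(1.09, 0.07), cycle_dur = c(1.1, 0.05),
      n_drop = 0
    ),
    expt2 = list(
      n_participants = 10, n_trials = 1, n_cycles = 12,
      keep = 10, min_cycles = 11,
      stature = c(1.81, 0.05), leg = c(0.96, 0.05),
      rel_speed = c(1.01, 0.12), cycle_dur = c(1.1, 0.06),
      n_drop = 3
    ),
    stop("unknown design: ", design, call. = FALSE)
  )
}

#' Generate a full synthetic study design
#'
#' Creates every walk trial of one of the two emulated study designs (or a
#' reduced variant), with per-participant anthropometry and gait baselines,
#' per-condition effect offsets, and complete ground truth for events,
#' stride lengths, sway amplitudes and imposed phase lags. Per-participant
#' variation enters through random intercepts on cycle duration, relative
#' speed, sway amplitude (log-normal) and phase lag, plus small trial-level
#' jitter on relative speed and phase lag.
#'
#' @param design `"expt1"` (9 participants, 2 trials/condition, 5 analyzed
#'   cycles each) or `"expt2"` (10 participants, 1 longer trial/condition,
#'   10 analyzed cycles, three designated cycles discarded).
#' @param base_params [gait_sim_params()] defaults for the no-load state;
#'   design presets override `n_cycles`, anthropometry and timing draws.
#' @param effects [effect_preset()] of condition offsets (default
#'   [preset_table3()]).
#' @param master_seed Integer master seed; per-trial seeds derive from it.
#' @param n_participants Override the preset participant count (reduced
#'   designs for quick runs).
#' @param n_cycles Override the preset number of complete cycles per trial;
#'   rejected when fewer than the design's analysis policy requires.
#' @param dir If non-`NULL`, write sensor streams, manifest, anthropometry
#'   and ground-truth sidecar tables as delimited text under this
#'   directory; the manifest then carries file paths.
#' @param amp_cv Between-participant log-normal CV of sway amplitudes.
#' @param lag_sd_deg Between-participant SD of phase lags (degrees).
#' @param trial_lag_sd_deg Trial-level phase-lag jitter (degrees).
#' @param trial_rs_sd Trial-level relative-speed jitter.
#' @return A list: `manifest` (one row per trial; includes file paths when
#'   written), `anthropometry`, `trials` (list of [generate_trial()]
#'   outputs, `NULL`ed when written to disk), `truth_cycles` (tibble of
#'   per-cycle ground truth keyed by trial), `truth_lags` (imposed per-trial
#'   phase lags), `drop_list` (tibble of discarded cycles, `expt2` only) and
#'   `design`.
#' @export
generate_design <- function(design = c("expt1", "expt2"),
                            base_params = gait_sim_params(),
                            effects = preset_table3(),
                            master_seed = 1L,
                            n_participants = NULL,
                            n_cycles = NULL,
                            dir = NULL,
                            amp_cv = 0.12,
                            lag_sd_deg = 8,
                            trial_lag_sd_deg = 3,
                            trial_rs_sd = 0.02) {
  design <- match.arg(design)
  spec <- design_spec(design)
  if (!is.null(n_participants)) spec$n_participants <- n_participants
  if (!is.null(n_cycles)) spec$n_cycles <- n_cycles
  if (spec$n_cycles < spec$min_cycles) {
    stop(
      "design '", design, "' requires at least ", spec$min_cycles,
      " complete cycles per trial (analyzed cycles 2-", spec$keep + 1,
      "); got n_cycles = ", spec$n_cycles,
      call. = FALSE
    )
  }
  write_out <- !is.null(dir)
  if (write_out) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  participants <- sprintf("P%02d", seq_len(spec$n_participants))
  anthro <- local_seed(derive_seed(master_seed, 0), {
    stature <- rnorm(spec$n_participants, spec$stature[1], spec$stature[2])
    leg <- pmin(
      rnorm(spec$n_participants, spec$leg[1], spec$leg[2]),
      0.62 * stature
    )
    tibble::tibble(
      participant = participants,
      stature_m = round(stature, 3),
      leg_length_m = round(leg, 3),
      thigh_length_m = round(base_params$template$thigh_fraction * leg, 3),
      shank_length_m = round(base_params$template$shank_fraction * leg, 3)
    )
  })
  subj <- local_seed(derive_seed(master_seed, 1), {
    tibble::tibble(
      participant = participants,
      rs_i = rnorm(spec$n_participants, spec$rel_speed[1], spec$rel_speed[2]),
      dur_i = rnorm(spec$n_participants, spec$cycle_dur[1], spec$cycle_dur[2]),
      # independent amplitude factors per site and plane so that no
      # artificial cross-parameter correlation is imposed
      amp_i = lapply(seq_len(spec$n_participants), function(i) {
        list(
          T6 = exp(rnorm(3, 0, amp_cv)),
          S1 = exp(rnorm(3, 0, amp_cv))
        )
      }),
      lag_i = rnorm(spec$n_participants, 0, lag_sd_deg)
    )
  })

  grid <- tidyr::expand_grid(
    participant = participants,
    carry_mode = factor(MODES, levels = MODES),
    load = factor(names(LOAD_LEVELS), levels = names(LOAD_LEVELS)),
    trial = seq_len(spec$n_trials)
  )
  grid$load_kg <- unname(LOAD_LEVELS[as.character(grid$load)])
  grid$trial_seed <- vapply(
    seq_len(nrow(grid)),
    function(i) derive_seed(master_seed, 100 + i),
    integer(1)
  )

  trials <- vector("list", nrow(grid))
  truth_cycles <- vector("list", nrow(grid))
  truth_lags <- vector("list", nrow(grid))
  path_cols <- matrix(NA_character_, nrow(grid), 4,
    dimnames = list(NULL, c("t6_file", "s1_file", "thigh_r_file", "shank_r_file"))
  )
  site_file <- c(
    T6 = "t6_file", S1 = "s1_file",
    thigh_R = "thigh_r_file", shank_R = "shank_r_file"
  )

  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    si <- subj[subj$participant == row$participant, ]
    ai <- anthro[anthro$participant == row$participant, ]
    jit <- local_seed(derive_seed(row$trial_seed, 1), {
      list(rs = rnorm(1, 0, trial_rs_sd), lag = rnorm(1, 0, trial_lag_sd_deg))
    })
    # self-selected speed eases off slightly with heavier loads
    rs_trial <- si$rs_i + jit$rs -
      0.005 * (match(row$load, names(LOAD_LEVELS)) - 1)
    p <- base_params
    p$n_cycles <- as.integer(spec$n_cycles)
    p$cycle_duration_s <- si$dur_i
    p$leg_length_m <- ai$leg_length_m
    p$thigh_length_m <- ai$thigh_length_m
    p$shank_length_m <- ai$shank_length_m
    p$rel_speed <- rs_trial
    p$stride_length_m <- rs_trial * ai$leg_length_m * si$dur_i
    amp_fac <- si$amp_i[[1]]
    p$sway_amplitude_deg <- lapply(
      setNames(names(p$sway_amplitude_deg), names(p$sway_amplitude_deg)),
      function(site) p$sway_amplitude_deg[[site]] * amp_fac[[site]]
    )
    lags <- pmin(180, pmax(0, p$phase_lag_deg + si$lag_i + jit$lag))
    names(lags) <- names(p$phase_lag_deg)
    p$phase_lag_deg <- lags
    p$seed <- derive_seed(row$trial_seed, 2)
    tr <- generate_trial(p,
      effects = effects,
      condition = list(carry_mode = row$carry_mode, load = row$load)
    )
    keys <- row[c("participant", "carry_mode", "load", "trial")]
    truth_cycles[[i]] <- dplyr::bind_cols(keys, tr$truth$cycles)
    truth_lags[[i]] <- dplyr::bind_cols(
      keys,
      tibble::as_tibble(as.list(tr$truth$phase_lag_deg))
    )
    if (write_out) {
      stem <- sprintf(
        "%s_%s_%s_t%d", row$participant, row$carry_mode, row$load, row$trial
      )
      for (site in names(tr$streams)) {
        f <- file.path(dir, paste0(stem, "_", tolower(site), ".csv"))
        write_sensor_stream(tr$streams[[site]], f)
        path_cols[i, site_file[[site]]] <- f
      }
      trials[i] <- list(NULL)
    } else {
      trials[[i]] <- tr
    }
  }

  manifest <- grid
  if (write_out) {
    manifest <- dplyr::bind_cols(manifest, tibble::as_tibble(path_cols))
  }

  drop_list <- tibble::tibble(
    participant = character(), carry_mode = character(),
    load = character(), trial = integer(), cycle = integer()
  )
  if (spec$n_drop > 0) {
    drop_idx <- local_seed(derive_seed(master_seed, 2), {
      sample(nrow(grid), spec$n_drop)
    })
    drop_list <- dplyr::mutate(
      grid[drop_idx, c("participant", "carry_mode", "load", "trial")],
      carry_mode = as.character(.data$carry_mode),
      load = as.character(.data$load),
      cycle = 6L
    )
  }

  truth_cycles <- dplyr::bind_rows(truth_cycles)
  truth_lags <- dplyr::bind_rows(truth_lags)
  if (write_out) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    data.table::fwrite(anthro, file.path(dir, "anthropometry.csv"))
    data.table::fwrite(
      as.data.frame(truth_cycles),
      file.path(dir, "truth_cycles.csv")
    )
    data.table::fwrite(
      as.data.frame(truth_lags),
      file.path(dir, "truth_lags.csv")
    )
    if (nrow(drop_list) > 0) {
      data.table::fwrite(as.data.frame(drop_list), file.path(dir, "drop_list.csv"))
    }
  }

  list(
    design = design,
    manifest = manifest,
    anthropometry = anthro,
    trials = trials,
    truth_cycles = truth_cycles,
    truth_lags = truth_lags,
    drop_list = drop_list,
    keep = spec$keep
  )
}

#' Simulate a trial-level response table for model calibration
#'
#' Draws one response parameter directly at the trial level of the first
#' study design (participants x modes x loads x trials), with participant
#' random intercepts, participant-level covariate slopes, a
#' participant-by-condition interaction component (the repeated-measures
#' correlation between a condition's trials) and trial noise. Used for
#' type-I-error and power calibration of [fit_gait_lmm()] without running
#' the signal pipeline.
#'
#' @param n_participants,n_trials Design size (defaults: 9 and 2).
#' @param cell_means Optional named numeric vector of condition-cell
#'   offsets, names `mode.load` (e.g. `side.H`); defaults to all zero
#'   (null data).
#' @param mu Grand mean of the response.
#' @param beta_crs Fixed slope of the centered-relative-speed covariate.
#' @param sd_participant,sd_slope,sd_cell,sd_trial Variance components:
#'   participant intercept SD, participant covariate-slope SD,
#'   participant-by-condition SD and residual trial SD.
#' @param seed Seed.
#' @return Tibble with `participant`, `carry_mode`, `load`,
#'   `trial`, `centered_relative_speed` and `y`.
#' @export
simulate_trial_table <- function(n_participants = 9, n_trials = 2,
                                 cell_means = NULL,
                                 mu = 100, beta_crs = 20,
                                 sd_participant = 10, sd_slope = 5,
                                 sd_cell = 8, sd_trial = 6,
                                 seed = NULL) {
  local_seed(seed, {
    participants <- sprintf("P%02d", seq_len(n_participants))
    b0 <- rnorm(n_participants, 0, sd_participant)
    b1 <- rnorm(n_participants, 0, sd_slope)
    rs_i <- rnorm(n_participants, 1.09, 0.07)
    tab <- tidyr::expand_grid(
      participant = participants,
      carry_mode = factor(MODES, levels = MODES),
      load = factor(names(LOAD_LEVELS), levels = names(LOAD_LEVELS)),
      trial = seq_len(n_trials)
    )
    pidx <- match(tab$participant, participants)
    cell_key <- paste(tab$carry_mode, tab$load, sep = ".")
    pc_key <- paste(tab$participant, cell_key)
    u_pc <- rnorm(length(unique(pc_key)), 0, sd_cell)
    names(u_pc) <- unique(pc_key)
    rs <- rs_i[pidx] + rnorm(nrow(tab), 0, 0.02)
    crs <- rs - mean(rs)
    eff <- if (is.null(cell_means)) 0 else {
      unname(ifelse(is.na(cell_means[cell_key]), 0, cell_means[cell_key]))
    }
    tab$centered_relative_speed <- crs
    tab$y <- mu + eff + b0[pidx] + b1[pidx] * crs + u_pc[pc_key] +
      rnorm(nrow(tab), 0, sd_trial)
    tab
  })
}
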