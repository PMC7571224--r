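# End-to-end processing: streams -> filtered signals -> gait events ->
# per-cycle displacement -> 11 gait parameters per analyzed cycle.

filter_stream <- function(stream, cfg) {
  pp <- cfg$preprocess
  out <- as.data.frame(stream)
  for (col in c("gyro_x_dps", "gyro_y_dps", "gyro_z_dps")) {
    out[[col]] <- butter_filter(out[[col]], attr(stream, "fs"),
      pp$lowpass_hz,
      type = "low", order = pp$filter_order
    )
  }
  out
}

#' Process one walk trial into per-cycle gait parameters
#'
#' Runs the full single-trial pipeline: zero-phase 2 Hz low-pass filtering
#' of every channel, gait-event detection on the shank sagittal channel,
#' trial-level gyro-bias removal (mean over the detected heel-strike span),
#' per-cycle integration to angular displacement (or the trial-level
#' high-passed alternative if configured), and computation of the 11 gait
#' parameters: cycle duration, stride length, six peak-to-peak ROMs (T6 and
#' S1 in coronal, transverse and sagittal planes) and three thoracic-pelvic
#' mean relative phase angles.
#'
#' @param streams Named list of [sensor_stream()]s; `shank_R` is required,
#'   `T6` and `S1` enable sway/coordination parameters, `thigh_R`
#'   additionally enables stride length.
#' @param anthro One-row anthropometry (list/tibble with `leg_length_m`,
#'   `thigh_length_m`, `shank_length_m`).
#' @param config Pipeline configuration.
#' @param skip_first,keep Cycle-selection policy (see [segment_cycles()]).
#' @param keep_rp Keep per-frame relative-phase trajectories as
#'   list-columns `rp_coronal`, `rp_transverse`, `rp_sagittal` (for
#'   ensemble curves).
#' @return Tibble with one row per analyzed cycle: `cycle`,
#'   `cycle_duration_s`, `stride_length_m`, `walking_speed_ms`,
#'   `relative_speed`, six `rom_*` and three `mrp_*` columns, and a `valid`
#'   flag (duration gate and defined phase).
#' @export
process_trial <- function(streams, anthro, config = default_config(),
                          skip_first = 1, keep = 5, keep_rp = FALSE) {
  if (!"shank_R" %in% names(streams)) {
    stop("shank_R stream is required for gait-event detection", call. = FALSE)
  }
  pp <- config$preprocess
  fs <- attr(streams$shank_R, "fs")
  t <- streams$shank_R$time_s

  filt <- lapply(streams, filter_stream, cfg = config)
  events <- detect_gait_events(filt$shank_R$gyro_y_dps, fs,
    t = t, config = config
  )
  cycles <- segment_cycles(events, skip_first = skip_first, keep = keep)

  # trial-level gyro-bias estimate over an integer number of cycles
  hs <- events$heel_strikes
  span <- t >= hs[1] & t <= hs[length(hs)]
  debias <- function(x) {
    if (isTRUE(pp$debias)) x - mean(x[span]) else x
  }

  dur <- diff(hs)[cycles]
  out <- tibble::tibble(
    cycle = cycles,
    cycle_duration_s = dur,
    valid = dur >= pp$cycle_gate_s[1] & dur <= pp$cycle_gate_s[2]
  )

  # stride length (thigh + shank sagittal channels); rotations are
  # integrated from the bias-corrected raw signal unless configured to use
  # the filtered one
  if (all(c("thigh_R", "shank_R") %in% names(filt))) {
    src <- if (isTRUE(config$stride$use_filtered)) filt else streams
    sl <- stride_lengths(
      debias(src$thigh_R$gyro_y_dps), debias(src$shank_R$gyro_y_dps),
      t, events,
      cycles = cycles,
      thigh_length_m = anthro$thigh_length_m,
      shank_length_m = anthro$shank_length_m,
      fs = fs, config = config
    )
    out$stride_length_m <- sl$stride_length_m[match(cycles, sl$cycle)]
  } else {
    out$stride_length_m <- NA_real_
  }
  out$walking_speed_ms <- out$stride_length_m / out$cycle_duration_s
  out$relative_speed <- relative_speed(
    out$stride_length_m, out$cycle_duration_s, anthro$leg_length_m
  )

  if (all(c("T6", "S1") %in% names(filt))) {
    segs <- list()
    for (site in c("T6", "S1")) {
      for (plane in names(PLANES)) {
        omega <- debias(filt[[site]][[axis_col(plane)]])
        if (isTRUE(pp$highpass)) {
          theta_trial <- trial_displacement_highpassed(
            omega, fs,
            highpass_hz = pp$highpass_hz, order = pp$filter_order
          )
          seg <- per_cycle_displacement(omega, t, events, fs,
            cycle_gate_s = pp$cycle_gate_s
          )
          # replace per-cycle integrals by slices of the high-passed
          # trial-level displacement over the same sample windows
          seg$theta <- purrr::map2(seg$start_s, seg$end_s, function(a, b) {
            i0 <- min(max(round((a - t[1]) * fs) + 1, 1), length(t))
            i1 <- min(max(round((b - t[1]) * fs) + 1, 1), length(t))
            theta_trial[i0:i1]
          })
        } else {
          seg <- per_cycle_displacement(omega, t, events, fs,
            cycle_gate_s = pp$cycle_gate_s
          )
        }
        segs[[paste(site, plane, sep = ".")]] <- seg
      }
    }
    for (site in c("T6", "S1")) {
      for (plane in names(PLANES)) {
        seg <- segs[[paste(site, plane, sep = ".")]]
        col <- paste0("rom_", plane, "_", tolower(site))
        out[[col]] <- vapply(
          cycles,
          function(i) rom(seg$theta[[match(i, seg$cycle)]]),
          numeric(1)
        )
      }
    }
    for (plane in names(PLANES)) {
      seg_t6 <- segs[[paste("T6", plane, sep = ".")]]
      seg_s1 <- segs[[paste("S1", plane, sep = ".")]]
      mrp_col <- paste0("mrp_", plane)
      rp_col <- paste0("rp_", plane)
      vals <- lapply(cycles, function(i) {
        j6 <- match(i, seg_t6$cycle)
        j1 <- match(i, seg_s1$cycle)
        mean_relative_phase(
          seg_t6$omega[[j6]], seg_t6$theta[[j6]],
          seg_s1$omega[[j1]], seg_s1$theta[[j1]],
          convention = config$phase$convention
        )
      })
      out[[mrp_col]] <- vapply(
        vals,
        function(v) if (is.null(v)) NA_real_ else v$mrp_deg,
        numeric(1)
      )
      if (keep_rp) {
        out[[rp_col]] <- lapply(vals, function(v) if (is.null(v)) NULL else v$rp)
      }
    }
    out$valid <- out$valid & !is.na(out$mrp_coronal)
  }
  attr(out, "events") <- events
  out
}

load_streams_from_row <- function(row, expected_fs, fs_tolerance) {
  file_cols <- c(
    T6 = "t6_file", S1 = "s1_file",
    thigh_R = "thigh_r_file", shank_R = "shank_r_file"
  )
  streams <- list()
  for (site in names(file_cols)) {
    path <- row[[file_cols[[site]]]]
    if (!is.null(path) && !is.na(path) && nzchar(path)) {
      streams[[site]] <- read_sensor_stream(path, site,
        expected_fs = expected_fs, fs_tolerance = fs_tolerance
      )
    }
  }
  streams
}

finalize_features <- function(rows, drop_list = NULL) {
  features <- dplyr::bind_rows(rows)
  if (!is.null(drop_list) && nrow(drop_list) > 0) {
    features <- dplyr::anti_join(
      features,
      dplyr::mutate(drop_list,
        carry_mode = as.character(.data$carry_mode),
        load = as.character(.data$load)
      ),
      by = c("participant", "carry_mode", "load", "trial", "cycle")
    )
  }
  features$carry_mode <- factor(features$carry_mode, levels = MODES)
  features$load <- factor(features$load, levels = names(LOAD_LEVELS))
  center_relative_speed(features)
}

#' Process a manifest of recorded trials
#'
#' Reads each trial's sensor streams, runs [process_trial()], and returns
#' the tidy per-cycle feature table with the grand-mean-centered
#' relative-speed covariate. Manifests containing shared no-load rows
#' (`carry_mode = "none"`) are expanded across modes first (see
#' [expand_shared_noload()]).
#'
#' @param manifest Manifest tibble ([read_manifest()]) with stream file
#'   paths.
#' @param anthropometry Anthropometry tibble ([read_anthropometry()]).
#' @param config Pipeline configuration.
#' @param skip_first,keep Cycle-selection policy.
#' @param drop_list Optional tibble of cycles to discard
#'   (`participant`, `carry_mode`, `load`, `trial`, `cycle`).
#' @param keep_rp Keep per-frame relative-phase list-columns.
#' @return Per-cycle feature tibble.
#' @export
process_manifest <- function(manifest, anthropometry,
                             config = default_config(),
                             skip_first = 1, keep = 5,
                             drop_list = NULL, keep_rp = FALSE) {
  manifest <- expand_shared_noload(manifest)
  pp <- config$preprocess
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    anthro <- anthropometry[anthropometry$participant == row$participant, ]
    if (nrow(anthro) != 1) {
      stop("anthropometry missing for participant ", row$participant,
        call. = FALSE
      )
    }
    streams <- load_streams_from_row(row, pp$fs_hz, pp$fs_tolerance)
    feats <- process_trial(streams, anthro,
      config = config,
      skip_first = skip_first, keep = keep, keep_rp = keep_rp
    )
    dplyr::bind_cols(
      tibble::tibble(
        participant = row$participant,
        carry_mode = as.character(row$carry_mode),
        load = as.character(row$load),
        load_kg = row$load_kg %||% unname(LOAD_LEVELS[as.character(row$load)]),
        trial = row$trial
      ),
      feats
    )
  })
  finalize_features(rows, drop_list)
}

#' Process a generated synthetic design end-to-end
#'
#' Applies the design's cycle-selection policy (cycles 2-6 for the first
#' design, 2-11 for the second) and its drop list, returning the same
#' feature table as [process_manifest()]. In-memory trials are processed
#' directly; designs written to disk are processed through their files.
#'
#' @param design_obj Output of [generate_design()].
#' @param config Pipeline configuration.
#' @param keep_rp Keep per-frame relative-phase list-columns.
#' @return Per-cycle feature tibble.
#' @export
process_design <- function(design_obj, config = default_config(),
                           keep_rp = FALSE) {
  manifest <- design_obj$manifest
  in_memory <- !is.null(design_obj$trials) &&
    !is.null(design_obj$trials[[1]])
  if (!in_memory) {
    return(process_manifest(
      manifest, design_obj$anthropometry,
      config = config,
      skip_first = 1, keep = design_obj$keep,
      drop_list = design_obj$drop_list, keep_rp = keep_rp
    ))
  }
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    anthro <- design_obj$anthropometry[
      design_obj$anthropometry$participant == row$participant,
    ]
    feats <- process_trial(design_obj$trials[[i]]$streams, anthro,
      config = config,
      skip_first = 1, keep = design_obj$keep, keep_rp = keep_rp
    )
    dplyr::bind_cols(
      tibble::tibble(
        participant = row$participant,
        carry_mode = as.character(row$carry_mode),
        load = as.character(row$load),
        load_kg = row$load_kg,
        trial = row$trial
      ),
      feats
    )
  })
  finalize_features(rows, design_obj$drop_list)
}
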