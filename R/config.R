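#' Default pipeline configuration
#'
#' All numeric constants used by the pipeline live here, grouped into the
#' sections `preprocess`, `events`, `stride`, `phase`, `stats` and `simulate`.
#' [load_config()] merges a user YAML file over these defaults.
#'
#' Key defaults and their meaning:
#' \describe{
#'   \item{preprocess}{`fs_hz = 80` nominal sampling rate; second-order
#'     zero-phase Butterworth low-pass at `lowpass_hz = 2` applied to all raw
#'     angular velocity; optional second-order high-pass at
#'     `highpass_hz = 0.75` applied to trial-level integrated displacement
#'     when `highpass = TRUE` (off by default: the default drift control is
#'     per-cycle re-integration plus trial-level bias removal, `debias =
#'     TRUE`). `cycle_gate_s = c(0.4, 2.5)` flags physiologically implausible
#'     cycle durations; `n_norm_points = 101` is the percent-gait-cycle grid.}
#'   \item{events}{Mid-swing peaks must exceed `peak_prominence_frac = 0.4`
#'     of the 95th percentile of |angular velocity| and be separated by
#'     `min_peak_separation_s = 0.6` (just over half of the fastest
#'     plausible cadence, so secondary stance maxima are suppressed in
#'     favour of the taller mid-swing peak); heel-strike / toe-off minima are
#'     searched within `minimum_window_s = 0.35` of each peak;
#'     `refine_subsample = TRUE` applies parabolic sub-sample refinement.}
#'   \item{stride}{Chord-length double-segment geometry; rotations above
#'     `max_rotation_deg = 120` are flagged implausible. Segment rotations
#'     are integrated from the bias-corrected raw signal by default
#'     (`use_filtered = FALSE`): the 2 Hz smoothing serves event detection,
#'     while sub-phase rotation integrals are noise-robust already and a
#'     heavy low-pass biases them. With `use_filtered = TRUE` the filtered
#'     signal is integrated and `gain_compensation = TRUE` divides by the
#'     known two-pass low-pass gain at the trial's stride frequency.}
#'   \item{phase}{`convention = "absolute"` averages |wrapped difference|
#'     (signed mode available); normalization maps each cycle signal onto
#'     \[-1, 1\].}
#'   \item{stats}{Satterthwaite denominator df, Bonferroni families as
#'     described in [bonferroni_contrasts()], `alpha = 0.05`.}
#'   \item{simulate}{Waveform template amplitudes and paddings used by the
#'     synthetic generator; see [gait_sim_params()].}
#' }
#'
#' @return Nested named list of configuration sections.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$preprocess$lowpass_hz
default_config <- function() {
  list(
    preprocess = list(
      fs_hz = 80,
      fs_tolerance = 0.01,
      lowpass_hz = 2.0,
      highpass_hz = 0.75,
      filter_order = 2,
      highpass = FALSE,       # default path: per-cycle re-integration
      debias = TRUE,          # subtract trial-level gyro bias before integrating
      cycle_gate_s = c(0.4, 2.5),
      n_norm_points = 101
    ),
    events = list(
      peak_prominence_frac = 0.4,
      min_peak_separation_s = 0.6,
      minimum_window_s = 0.35,
      auto_flip = TRUE,
      refine_subsample = TRUE
    ),
    stride = list(
      max_rotation_deg = 120,
      use_filtered = FALSE,
      gain_compensation = TRUE,
      stance_fraction = 0.6   # used by the generator's ground truth only
    ),
    phase = list(
      convention = "absolute",  # or "signed"
      unwrap_before_diff = FALSE
    ),
    stats = list(
      alpha = 0.05,
      ddf_method = "Satterthwaite",
      adjust = "bonferroni"
    ),
    simulate = list(
      # three-harmonic shank sagittal waveform: ~300 deg/s mid-swing peak,
      # deep negative minima flanking it at heel-strike and toe-off
      shank_harmonics_dps = c(29.35, -73.39, 197.26),
      shank_phases = c(0.8, 0.05, 0.1333333),
      pad_pre_cycles = 0.45,
      pad_post_cycles = 0.30,
      thigh_fraction = 0.53,     # of leg length
      shank_fraction = 0.47
    )
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a structured-text (YAML) configuration and merges it over
#' [default_config()]: sections and keys absent from the file keep their
#' defaults, unknown keys are rejected.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Configuration list as in [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) {
    return(cfg)
  }
  bad_sections <- setdiff(names(user), names(cfg))
  if (length(bad_sections) > 0) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "),
      call. = FALSE
    )
  }
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad) > 0) {
      stop(
        "unknown key(s) in config section '", sec, "': ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pp <- cfg$preprocess
  stopifnot(
    pp$fs_hz > 0,
    pp$lowpass_hz > 0, pp$lowpass_hz < pp$fs_hz / 2,
    pp$highpass_hz > 0, pp$highpass_hz < pp$fs_hz / 2,
    pp$filter_order >= 1,
    length(pp$cycle_gate_s) == 2, pp$cycle_gate_s[1] < pp$cycle_gate_s[2],
    pp$n_norm_points >= 3
  )
  stopifnot(
    cfg$events$peak_prominence_frac > 0, cfg$events$peak_prominence_frac <= 1,
    cfg$events$min_peak_separation_s > 0,
    cfg$events$minimum_window_s > 0
  )
  stopifnot(cfg$phase$convention %in% c("absolute", "signed"))
  cfg
}
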