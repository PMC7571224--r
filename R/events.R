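# Gait-event detection from the shank sagittal gyroscope channel.
#
# Mid-swing is the prominent positive peak of the shank sagittal angular
# velocity; heel-strike is the first local minimum after each mid-swing
# peak and toe-off the last local minimum before it. A gait cycle is the
# interval between two consecutive heel-strikes.

local_extrema <- function(x, minima = FALSE) {
  if (minima) x <- -x
  n <- length(x)
  if (n < 3) {
    return(integer())
  }
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# parabolic sub-sample refinement of an extremum at index i
refine_extremum <- function(x, i) {
  if (i <= 1 || i >= length(x)) {
    return(i)
  }
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (abs(denom) < .Machine$double.eps) {
    return(i)
  }
  delta <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  i + max(-0.5, min(0.5, delta))
}

#' Detect heel-strike and toe-off events from shank angular velocity
#'
#' Operates on the low-pass-filtered sagittal (y-axis) angular velocity of
#' the right shank. Candidate mid-swing events are positive local maxima
#' exceeding a prominence threshold (a fraction of the trial's 95th
#' percentile of |angular velocity|) with a minimum temporal separation;
#' for each peak, heel-strike is the first local minimum within a search
#' window after the peak and toe-off the last local minimum within the
#' window before it. A polarity auto-flip handles inverted sensor
#' mounting. Event times are refined to sub-sample precision by parabolic
#' interpolation.
#'
#' @param omega Filtered shank sagittal angular velocity (degrees/s).
#' @param fs Sampling rate (Hz).
#' @param t Optional time vector (s); defaults to `(0:(n-1))/fs`.
#' @param config Pipeline configuration; uses the `events` section.
#' @return A `gait_events` list: `heel_strikes`, `toe_offs`,
#'   `mid_swing_peaks` (times in s), the matching `*_idx` sample indices
#'   (1-based, nearest sample), `flipped`, and `n_cycles`.
#' @export
detect_gait_events <- function(omega, fs, t = NULL,
                               config = default_config()) {
  ev <- config$events
  n <- length(omega)
  if (n < 2 * fs) {
    stop("need at least 2 s of data for gait detection", call. = FALSE)
  }
  if (is.null(t)) t <- (seq_len(n) - 1L) / fs
  x <- omega
  flipped <- FALSE
  # polarity check on trimmed quantiles: robust to isolated edge excursions
  # of the zero-phase filter at the trial boundaries
  if (isTRUE(ev$auto_flip) &&
    quantile(x, 0.99, names = FALSE) < -quantile(x, 0.01, names = FALSE)) {
    x <- -x
    flipped <- TRUE
  }
  thr <- ev$peak_prominence_frac * quantile(abs(x), 0.95, names = FALSE)
  cand <- local_extrema(x)
  cand <- cand[x[cand] >= thr & x[cand] > 0]
  if (length(cand) == 0 || thr <= 0) {
    stop("no gait detected: no mid-swing peak exceeds the prominence threshold",
      call. = FALSE
    )
  }
  # enforce minimum separation, keeping the taller peak of any close pair
  min_sep <- ev$min_peak_separation_s * fs
  keep <- logical(length(cand))
  for (i in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < min_sep)) keep[i] <- TRUE
  }
  peaks <- sort(cand[keep])

  mins <- local_extrema(x, minima = TRUE)
  win <- round(ev$minimum_window_s * fs)
  place <- function(i) {
    if (isTRUE(ev$refine_subsample)) refine_extremum(x, i) else i
  }
  hs_idx <- rep(NA_real_, length(peaks))
  to_idx <- rep(NA_real_, length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    after <- mins[mins > p & mins <= p + win]
    before <- mins[mins < p & mins >= p - win]
    if (length(after) > 0) hs_idx[k] <- place(after[1])
    if (length(before) > 0) to_idx[k] <- place(before[length(before)])
  }
  peak_ref <- vapply(peaks, place, numeric(1))

  ok_hs <- !is.na(hs_idx)
  if (sum(ok_hs) < 1) {
    stop("no gait detected: no heel-strike minima near mid-swing peaks",
      call. = FALSE
    )
  }
  dropped <- sum(!ok_hs)
  if (dropped > 0) {
    warning(dropped, " mid-swing peak(s) without a heel-strike minimum dropped",
      call. = FALSE
    )
  }
  hs <- hs_idx[ok_hs]
  to <- to_idx[ok_hs]
  pk <- peak_ref[ok_hs]

  idx_time <- function(i) {
    i0 <- floor(i)
    frac <- i - i0
    ifelse(i0 >= length(t), t[length(t)], t[i0] + frac * (t[pmin(i0 + 1, length(t))] - t[i0]))
  }
  hs_t <- idx_time(hs)
  to_t <- idx_time(to)
  pk_t <- idx_time(pk)

  # per-cycle invariant check: exactly one toe-off, toe-off before the
  # mid-swing peak of the same swing (the swing ending at the later HS)
  bad <- which(!is.na(to_t[-1]) & (to_t[-1] <= hs_t[-length(hs_t)] |
    to_t[-1] >= pk_t[-1]))
  if (length(bad) > 0) {
    warning(length(bad), " cycle(s) with invalid event pattern flagged",
      call. = FALSE
    )
  }
  structure(
    list(
      heel_strikes = hs_t,
      toe_offs = to_t[-1][!is.na(to_t[-1])],
      mid_swing_peaks = pk_t,
      heel_strike_idx = round(hs),
      toe_off_idx = round(to[-1][!is.na(to[-1])]),
      mid_swing_idx = round(pk),
      toe_off_by_peak = to_t, # aligned to peaks/heel-strikes, NA if missing
      flipped = flipped,
      n_cycles = length(hs_t) - 1L
    ),
    class = "gait_events"
  )
}

#' @export
print.gait_events <- function(x, ...) {
  cat(
    "<gait_events> ", length(x$heel_strikes), " heel-strikes, ",
    length(x$toe_offs), " toe-offs, ", x$n_cycles, " cycles",
    if (x$flipped) " (signal polarity flipped)", "\n",
    sep = ""
  )
  invisible(x)
}

#' Select analysis cycles from detected events
#'
#' The fixed study policy skips the first cycle (gait initiation) and keeps
#' the next `keep` cycles, i.e. cycles 2 to `keep + 1`; `keep = "all"`
#' keeps every detected cycle after the skipped ones.
#'
#' @param events A `gait_events` object (or anything with `heel_strikes`).
#' @param skip_first Number of initial cycles to skip (default 1).
#' @param keep Number of cycles to keep, or `"all"`.
#' @return Integer vector of selected cycle indices (1-based, cycle i runs
#'   from heel-strike i to heel-strike i+1).
#' @export
#' @examples
#' ev <- list(heel_strikes = 0:8 * 1.1)
#' segment_cycles(ev, keep = 5) # cycles 2..6
segment_cycles <- function(events, skip_first = 1, keep = 5) {
  n_cycles <- length(events$heel_strikes) - 1L
  if (identical(keep, "all")) {
    if (n_cycles <= skip_first) {
      stop("insufficient cycles: need more than ", skip_first, ", found ",
        n_cycles,
        call. = FALSE
      )
    }
    return(seq.int(skip_first + 1L, n_cycles))
  }
  needed <- skip_first + keep
  if (n_cycles < needed) {
    stop(
      "insufficient cycles: policy needs ", needed, " (skip ", skip_first,
      " + keep ", keep, "), found ", n_cycles,
      call. = FALSE
    )
  }
  seq.int(skip_first + 1L, skip_first + keep)
}

# two-pass (zero-phase) low-pass amplitude gain of an order-n Butterworth
butter2pass_gain <- function(f, fc, order = 2) {
  1 / (1 + (f / fc)^(2 * order))
}

#' Double-segment stride length per gait cycle
#'
#' Estimates stride length from thigh and shank sagittal angular velocity
#' using the double-segment gait model: the leg behaves as an inverted
#' double pendulum pivoting over the stance foot between heel-strike and
#' toe-off, and as a double pendulum swinging the foot forward between
#' toe-off and the next heel-strike, with left/right symmetry. Each
#' segment's rotation over a sub-phase is the integral of its sagittal
#' angular velocity, and contributes the chord length `2 L sin(dtheta/2)`
#' of a rigid segment of length `L` rotating by `dtheta`; the stance and
#' swing displacements sum to the stride.
#'
#' By default the rotation integrals are computed from the bias-corrected
#' raw signals (`use_filtered = FALSE`): integration is itself
#' noise-robust, while the 2 Hz smoothing used for event detection
#' attenuates genuine within-phase rotation. When `use_filtered = TRUE`
#' the filtered signal is integrated instead, and `gain_compensation`
#' divides the integrals by the known two-pass low-pass Butterworth gain
#' at the trial's stride frequency to undo the attenuation of the
#' fundamental.
#'
#' @param thigh_omega,shank_omega Filtered sagittal angular velocity
#'   (degrees/s) of the right thigh and shank over the whole trial.
#' @param t Time vector (s).
#' @param events `gait_events` from [detect_gait_events()].
#' @param cycles Integer cycle indices to evaluate (default: all).
#' @param thigh_length_m,shank_length_m Segment lengths (m).
#' @param fs Sampling rate (Hz).
#' @param config Pipeline configuration; uses `stride` and `preprocess`.
#' @return Tibble with `cycle`, `stride_length_m`, and `implausible`
#'   (TRUE when a segment rotation exceeded the plausibility bound).
#'   `stride_length_m` is `NA` when the thigh stream is missing.
#' @export
stride_lengths <- function(thigh_omega, shank_omega, t, events,
                           cycles = NULL,
                           thigh_length_m, shank_length_m, fs,
                           config = default_config()) {
  stopifnot(shank_length_m > 0)
  hs <- events$heel_strikes
  n_cycles <- length(hs) - 1L
  if (is.null(cycles)) cycles <- seq_len(n_cycles)
  to_by_peak <- events$toe_off_by_peak
  if (is.null(thigh_omega)) {
    return(tibble::tibble(
      cycle = cycles, stride_length_m = NA_real_, implausible = NA
    ))
  }
  stopifnot(thigh_length_m > 0)
  max_rot <- config$stride$max_rotation_deg
  gain <- 1
  if (isTRUE(config$stride$use_filtered) &&
    isTRUE(config$stride$gain_compensation)) {
    f_stride <- 1 / median(diff(hs))
    gain <- butter2pass_gain(
      f_stride, config$preprocess$lowpass_hz,
      config$preprocess$filter_order
    )
  }
  nearest <- function(x) pmin(pmax(round((x - t[1]) * fs) + 1L, 1L), length(t))
  seg_rot <- function(omega, t0, t1) {
    i0 <- nearest(t0)
    i1 <- nearest(t1)
    if (i1 <= i0) {
      return(NA_real_)
    }
    pracma::trapz(t[i0:i1], omega[i0:i1]) / gain
  }
  stride <- rep(NA_real_, length(cycles))
  implausible <- rep(NA, length(cycles))
  for (k in seq_along(cycles)) {
    i <- cycles[k]
    # toe-off of the swing that ends at heel-strike i+1
    to <- to_by_peak[i + 1]
    if (is.na(to) || to <= hs[i] || to >= hs[i + 1]) next
    rot <- c(
      seg_rot(thigh_omega, hs[i], to), # stance, thigh
      seg_rot(thigh_omega, to, hs[i + 1]), # swing, thigh
      seg_rot(shank_omega, hs[i], to), # stance, shank
      seg_rot(shank_omega, to, hs[i + 1]) # swing, shank
    )
    if (anyNA(rot)) next
    implausible[k] <- any(abs(rot) > max_rot)
    stride[k] <- chord_stride(rot[1:2], rot[3:4], thigh_length_m, shank_length_m)
  }
  tibble::tibble(
    cycle = cycles, stride_length_m = stride, implausible = implausible
  )
}

#' Relative walking speed
#'
#' Walking speed (stride length / cycle duration) normalized by leg length;
#' the covariate of the statistical models. [center_relative_speed()]
#' subtracts the grand mean over the analysis set.
#'
#' @param stride_length_m Stride length per cycle (m).
#' @param duration_s Cycle duration (s).
#' @param leg_length_m Participant leg length (m).
#' @return Relative speed (m/s per m of leg length, i.e. 1/s).
#' @export
#' @examples
#' relative_speed(1.40, 1.28, 0.94) # 1.164
relative_speed <- function(stride_length_m, duration_s, leg_length_m) {
  if (any(leg_length_m <= 0, na.rm = TRUE)) {
    stop("leg length must be positive", call. = FALSE)
  }
  if (any(duration_s <= 0, na.rm = TRUE)) {
    stop("cycle duration must be positive", call. = FALSE)
  }
  (stride_length_m / duration_s) / leg_length_m
}

#' @rdname relative_speed
#' @param features Feature tibble containing a `relative_speed` column.
#' @return For `center_relative_speed()`: the tibble with a
#'   `centered_relative_speed` column (grand-mean-centered over non-missing
#'   cycles).
#' @export
center_relative_speed <- function(features) {
  features$centered_relative_speed <-
    features$relative_speed - mean(features$relative_speed, na.rm = TRUE)
  features
}
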