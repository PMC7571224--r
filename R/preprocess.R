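#' Zero-phase Butterworth filtering
#'
#' Applies a second-order (by default) Butterworth filter forward and backward
#' so that the net phase response is zero. The signal is extended at both ends
#' by odd reflection and each pass starts from steady-state initial
#' conditions, so step/DC inputs produce no edge transients. The two-pass
#' amplitude response is \eqn{|H(f)|^2}, i.e. a low-pass passes DC with gain
#' exactly 1 and has gain 1/2 (-6 dB) at its cutoff frequency.
#'
#' @param x Numeric signal (regularly sampled).
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Cutoff frequency in Hz (must be below `fs/2`).
#' @param type `"low"` or `"high"`.
#' @param order Filter order of a single pass (default 2).
#' @return Filtered numeric vector, same length as `x`.
#' @export
#' @examples
#' fs <- 80
#' t <- seq(0, 5, by = 1 / fs)
#' x <- sin(2 * pi * 0.5 * t)
#' y <- butter_filter(x, fs, cutoff_hz = 2, type = "low")
#' max(abs(y)) # ~0.996: |H|^2 of an order-2 Butterworth at f/fc = 0.25
butter_filter <- function(x, fs, cutoff_hz, type = c("low", "high"),
                          order = 2) {
  type <- match.arg(type)
  stopifnot(is.numeric(x), fs > 0, cutoff_hz > 0, cutoff_hz < fs / 2)
  co <- signal::butter(order, cutoff_hz / (fs / 2), type = type)
  filtfilt_padded(co$b, co$a, x)
}

# Forward-backward filtering with odd-reflection padding and steady-state
# initial conditions (the standard zero-phase scheme). padlen follows the
# usual 3 * max(length(a), length(b)) rule.
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  padlen <- 3L * max(length(a), length(b))
  if (n <= padlen) {
    stop(
      "signal too short for zero-phase filtering: length ", n,
      " <= minimum ", padlen + 1L, " samples",
      call. = FALSE
    )
  }
  zi <- lfilter_zi(b, a)
  ext <- c(
    2 * x[1] - x[(padlen + 1L):2L],
    x,
    2 * x[n] - x[(n - 1L):(n - padlen)]
  )
  y <- .df2t_filter(b, a, ext, zi * ext[1])
  y <- rev(.df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

# Steady-state state vector of the direct-form-II-transposed filter for a
# unit step input, so filtering a constant yields that constant immediately.
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b)) - 1L
  a <- c(a, rep(0, m + 1L - length(a)))
  b <- c(b, rep(0, m + 1L - length(b)))
  if (abs(a[1] - 1) > 1e-12) {
    b <- b / a[1]
    a <- a / a[1]
  }
  # companion matrix of the monic polynomial a
  A <- matrix(0, m, m)
  A[1, ] <- -a[2:(m + 1L)]
  if (m > 1L) A[cbind(2:m, 1:(m - 1L))] <- 1
  B <- b[2:(m + 1L)] - a[2:(m + 1L)] * b[1]
  solve(diag(m) - t(A), B)
}

#' Integrate angular velocity to angular displacement
#'
#' Cumulative trapezoidal integration of an angular-velocity signal sampled
#' uniformly at `fs`, with the integration constant fixed so that the
#' displacement starts at zero.
#'
#' @param omega Angular velocity in degrees/s.
#' @param fs Sampling rate in Hz.
#' @return Angular displacement in degrees, same length as `omega`,
#'   starting at 0.
#' @export
#' @examples
#' th <- integrate_angular(rep(10, 161), fs = 80)
#' tail(th, 1) # 20 degrees after 2 s at 10 deg/s
integrate_angular <- function(omega, fs) {
  stopifnot(is.numeric(omega), fs > 0)
  if (length(omega) < 2) {
    return(rep(0, length(omega)))
  }
  drop(pracma::cumtrapz(omega)) / fs
}

#' Per-cycle angular displacement segments
#'
#' Integrates filtered angular velocity within each gait cycle, restarting
#' the integration at zero displacement at every cycle start. Restarting
#' bounds integration drift by the cycle duration (~1 s) instead of the trial
#' duration, which is the pipeline's primary drift control.
#'
#' @param omega Filtered angular velocity (degrees/s) for one sensor axis,
#'   covering the whole trial.
#' @param t Time vector in seconds, same length as `omega`.
#' @param events A `gait_events` object from [detect_gait_events()], or any
#'   list with a numeric `heel_strikes` element (times in seconds).
#' @param fs Sampling rate in Hz.
#' @param cycle_gate_s Length-2 numeric: cycles with durations outside this
#'   range are flagged invalid (kept in the output with `valid = FALSE`).
#' @return A tibble with one row per cycle: `cycle`, `start_s`, `end_s`,
#'   `duration_s`, `valid`, and list-columns `theta` (displacement, degrees)
#'   and `omega` (the velocity samples of the cycle).
#' @export
per_cycle_displacement <- function(omega, t, events, fs,
                                   cycle_gate_s = c(0.4, 2.5)) {
  hs <- events$heel_strikes
  if (length(hs) < 2) {
    return(tibble::tibble(
      cycle = integer(), start_s = numeric(), end_s = numeric(),
      duration_s = numeric(), valid = logical(),
      theta = list(), omega = list()
    ))
  }
  n_cyc <- length(hs) - 1L
  # nearest-sample indices of the (possibly sub-sample) heel-strike times
  idx <- pmin(pmax(round((hs - t[1]) * fs) + 1L, 1L), length(t))
  dur <- diff(hs)
  seg_omega <- lapply(seq_len(n_cyc), function(i) omega[idx[i]:idx[i + 1]])
  tibble::tibble(
    cycle = seq_len(n_cyc),
    start_s = hs[-length(hs)],
    end_s = hs[-1],
    duration_s = dur,
    valid = dur >= cycle_gate_s[1] & dur <= cycle_gate_s[2] &
      lengths(seg_omega) >= 4,
    theta = lapply(seg_omega, integrate_angular, fs = fs),
    omega = seg_omega
  )
}

#' Trial-level displacement with high-pass drift reduction
#'
#' The alternative drift-control path: integrate the filtered angular
#' velocity over the whole trial, then apply a zero-phase second-order
#' high-pass (0.75 Hz by default) to the displacement to suppress the
#' slowly growing integration drift. Note that a 0.75 Hz two-pass high-pass
#' also attenuates genuine sway at typical stride frequencies (~0.9 Hz) by
#' roughly 30%, which is why the per-cycle path is the package default.
#'
#' @inheritParams integrate_angular
#' @param highpass_hz High-pass cutoff in Hz.
#' @param order Filter order (single pass).
#' @return Angular displacement in degrees, same length as `omega`.
#' @export
trial_displacement_highpassed <- function(omega, fs, highpass_hz = 0.75,
                                          order = 2) {
  theta <- integrate_angular(omega, fs)
  butter_filter(theta, fs, highpass_hz, type = "high", order = order)
}

#' Resample a cycle segment onto a percent-gait-cycle grid
#'
#' Linear-interpolation resampling of a within-cycle signal onto `n_points`
#' equally spaced points spanning 0-100% of the gait cycle. Endpoints are
#' preserved exactly.
#'
#' @param y Numeric signal over one gait cycle.
#' @param n_points Number of grid points (default 101, i.e. every 1%).
#' @return Numeric vector of length `n_points`.
#' @export
#' @examples
#' time_normalize(seq(0, 1, length.out = 80))[c(1, 101)]
time_normalize <- function(y, n_points = 101) {
  stopifnot(length(y) >= 2, n_points >= 2)
  approx(
    x = seq(0, 1, length.out = length(y)),
    y = y,
    xout = seq(0, 1, length.out = n_points)
  )$y
}
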