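# Per-cycle sway (ROM) and thoracic-pelvic coordination (continuous
# relative phase) measures.

#' Peak-to-peak range of motion of a displacement segment
#'
#' @param theta Angular displacement (degrees) over one gait cycle.
#' @return `max(theta) - min(theta)` in degrees.
#' @export
#' @examples
#' rom(3 * sin(seq(0, 2 * pi, length.out = 88))) # ~6
rom <- function(theta) {
  if (length(theta) == 0 || all(is.na(theta))) {
    return(NA_real_)
  }
  max(theta, na.rm = TRUE) - min(theta, na.rm = TRUE)
}

# map a cycle signal onto [-1, 1]: v -> 2 (v - min) / (max - min) - 1
normalize_unit <- function(v) {
  r <- range(v)
  if (diff(r) <= .Machine$double.eps * max(1, abs(r[2]))) {
    return(NULL) # zero-amplitude: phase undefined
  }
  2 * (v - r[1]) / (r[2] - r[1]) - 1
}

#' Phase-portrait angle of a segment over one gait cycle
#'
#' Both the angular displacement and the angular velocity are
#' amplitude-normalized onto \[-1, 1\] over the cycle, and the phase angle
#' at each data frame is the four-quadrant arctangent of (normalized
#' velocity, normalized displacement), in degrees. The four-quadrant form
#' is required for phase angles beyond +/-90 degrees; the principal-branch
#' arctangent of the velocity/displacement ratio cannot represent the
#' out-of-phase regime.
#'
#' @param omega Angular velocity (degrees/s) over one cycle.
#' @param theta Angular displacement (degrees) over the same cycle, same
#'   length.
#' @return Per-frame phase angle in degrees in (-180, 180\], or `NULL` if
#'   either signal has zero amplitude over the cycle.
#' @export
phase_angle <- function(omega, theta) {
  stopifnot(length(omega) == length(theta))
  th <- normalize_unit(theta)
  om <- normalize_unit(omega)
  if (is.null(th) || is.null(om)) {
    return(NULL)
  }
  atan2(om, th) * 180 / pi
}

wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  # map -180 to +180 so the wrapped interval is (-180, 180]
  y[y == -180] <- 180
  y
}

#' Mean thoracic-pelvic relative phase over one gait cycle
#'
#' Computes the per-frame difference between the pelvic (S1) and thoracic
#' (T6) phase-portrait angles, wraps it to (-180, 180\] degrees, and
#' averages over the cycle. Under the default `"absolute"` convention the
#' absolute wrapped difference is averaged, yielding a value in
#' \[0, 180\] where 0 means perfectly in-phase (synchronized) and 180
#' anti-phase movement; `"signed"` averages the wrapped difference itself.
#'
#' @param t6_omega,t6_theta Thoracic velocity/displacement over the cycle.
#' @param s1_omega,s1_theta Pelvic velocity/displacement over the cycle.
#' @param convention `"absolute"` (default) or `"signed"`.
#' @return List with `mrp_deg` (the cycle mean) and `rp` (the per-frame
#'   wrapped relative phase, degrees), or `NULL` if phase is undefined for
#'   either site (zero-amplitude cycle).
#' @export
mean_relative_phase <- function(t6_omega, t6_theta, s1_omega, s1_theta,
                                convention = c("absolute", "signed")) {
  convention <- match.arg(convention)
  ph_t6 <- phase_angle(t6_omega, t6_theta)
  ph_s1 <- phase_angle(s1_omega, s1_theta)
  if (is.null(ph_t6) || is.null(ph_s1)) {
    return(NULL)
  }
  rp <- wrap180(ph_s1 - ph_t6) # pelvic minus thoracic
  mrp <- if (convention == "absolute") mean(abs(rp)) else mean(rp)
  list(mrp_deg = mrp, rp = rp)
}

#' Ensemble relative-phase curve over the gait cycle
#'
#' Averages per-frame absolute relative-phase trajectories, each
#' time-normalized onto a percent-gait-cycle grid, first across cycles
#' within a participant and then across participants (so unbalanced cycle
#' counts do not overweight any participant). The standard error is
#' computed across participant means.
#'
#' @param rp_cycles Tibble with list-column `rp` (per-frame relative phase
#'   per cycle, degrees) and a `participant` column; typically from
#'   [process_manifest()] with `keep_rp = TRUE`.
#' @param n_points Grid size (default 101 points, 0-100%).
#' @param condition Optional condition label attached to the output.
#' @param convention `"absolute"` (default) or `"signed"`.
#' @return A `gait_phase_curve` tibble: `pct` (0-100), `mean_deg`,
#'   `se_deg`, `n_participants`, `condition`.
#' @export
ensemble_phase_curve <- function(rp_cycles, n_points = 101,
                                 condition = NA_character_,
                                 convention = c("absolute", "signed")) {
  convention <- match.arg(convention)
  stopifnot(nrow(rp_cycles) >= 2, "rp" %in% names(rp_cycles))
  if (!"participant" %in% names(rp_cycles)) {
    rp_cycles$participant <- "P01"
  }
  tf <- if (convention == "absolute") abs else identity
  per_part <- rp_cycles |>
    dplyr::mutate(
      grid = purrr::map(.data$rp, ~ time_normalize(tf(.x), n_points))
    ) |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      grid = list(rowMeans(do.call(cbind, .data$grid))),
      .groups = "drop"
    )
  mat <- do.call(cbind, per_part$grid)
  n_p <- ncol(mat)
  if (n_p < 2) {
    warning("fewer than 2 participants: standard error not available",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    pct = seq(0, 100, length.out = n_points),
    mean_deg = rowMeans(mat),
    se_deg = if (n_p >= 2) apply(mat, 1, sd) / sqrt(n_p) else NA_real_,
    n_participants = n_p,
    condition = condition
  )
  class(out) <- c("gait_phase_curve", class(out))
  out
}
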