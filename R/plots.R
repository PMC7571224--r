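# ggplot2 displays for the pipeline's result types.

#' Plot an ensemble relative-phase curve
#'
#' Mean +/- SE thoracic-pelvic relative phase over the normalized gait
#' cycle, one ribbon per condition.
#'
#' @param object A `gait_phase_curve` tibble ([ensemble_phase_curve()]),
#'   or several row-bound together (distinguished by `condition`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gait_phase_curve
#' @export
autoplot.gait_phase_curve <- function(object, ...) {
  has_se <- any(is.finite(object$se_deg))
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$pct, y = .data$mean_deg,
      colour = .data$condition, fill = .data$condition
    )
  )
  if (has_se) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_deg - .data$se_deg,
        ymax = .data$mean_deg + .data$se_deg
      ),
      alpha = 0.25, colour = NA
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "Gait cycle (%)",
      y = "Thoracic-pelvic relative phase (deg)",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot estimated marginal means by mode and load
#'
#' Point-range display of the EMMs (+/- SE) for each carrying-mode and
#' load-level cell, at the mean of the centered relative-speed covariate.
#'
#' @param object An `emm_table` ([emm_table()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emm_table
#' @export
autoplot.emm_table <- function(object, ...) {
  d <- dplyr::filter(object, .data$carry_mode != "pooled")
  d$load <- factor(d$load, levels = names(LOAD_LEVELS))
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$load, y = .data$emmean,
      colour = .data$carry_mode, group = .data$carry_mode
    )
  ) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        ymin = .data$emmean - .data$se,
        ymax = .data$emmean + .data$se
      ),
      position = ggplot2::position_dodge(0.2)
    ) +
    ggplot2::labs(
      x = "Load level", y = attr(object, "response") %||% "EMM",
      colour = "Carrying mode"
    ) +
    ggplot2::theme_minimal()
}

#' Quick residual diagnostic plots for a fitted gait model
#'
#' @param x A `gait_lmm` object.
#' @param which `"qq"` or `"box"` (residuals by condition).
#' @return A ggplot object.
#' @export
plot_gait_diagnostics <- function(x, which = c("qq", "box")) {
  which <- match.arg(which)
  diag <- model_diagnostics(x)
  if (which == "qq") {
    ggplot2::ggplot(diag$residuals, ggplot2::aes(sample = .data$residual)) +
      ggplot2::stat_qq() +
      ggplot2::stat_qq_line() +
      ggplot2::labs(
        title = paste("Residual Q-Q:", x$response),
        x = "Theoretical quantiles", y = "Residuals"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(
      diag$residuals,
      ggplot2::aes(x = .data$load, y = .data$residual, fill = .data$carry_mode)
    ) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(
        title = paste("Residuals by condition:", x$response),
        x = "Load level", y = "Residuals", fill = "Carrying mode"
      ) +
      ggplot2::theme_minimal()
  }
}
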