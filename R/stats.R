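# Mixed-effects analysis of the nine sway/coordination parameters:
# carrying mode x load level (+ interaction) with centered relative speed
# as covariate, participant random intercept and covariate slope, and a
# participant-by-condition component carrying the repeated-measures
# (trial) correlation.

GAIT_PARAMS <- c(
  "rom_coronal_t6", "rom_coronal_s1",
  "rom_transverse_t6", "rom_transverse_s1",
  "rom_sagittal_t6", "rom_sagittal_s1",
  "mrp_coronal", "mrp_transverse", "mrp_sagittal"
)

#' Names of the nine sway and coordination parameters
#' @return Character vector of feature-table column names.
#' @export
gait_parameters <- function() GAIT_PARAMS

#' Aggregate per-cycle features to trial level
#'
#' Averages every gait parameter and the relative-speed covariate over the
#' analyzed cycles within each walk trial, the unit of the statistical
#' analysis. Invalid cycles are excluded from the means and counted in
#' `n_cycles_valid`.
#'
#' @param features Per-cycle feature tibble from [process_manifest()] /
#'   [process_design()].
#' @return Trial-level tibble, one row per (participant, carry_mode, load,
#'   trial), with the parameter means, `centered_relative_speed`
#'   re-centered over trials, and cycle counts.
#' @export
aggregate_trials <- function(features) {
  stopifnot(all(c("participant", "carry_mode", "load", "trial")
  %in% names(features)))
  num_cols <- intersect(
    c(
      "cycle_duration_s", "stride_length_m", "walking_speed_ms",
      "relative_speed", GAIT_PARAMS
    ),
    names(features)
  )
  if (!"valid" %in% names(features)) features$valid <- TRUE
  keys <- c("participant", "carry_mode", "load", "trial")
  counts <- features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_cycles = dplyr::n(),
      n_cycles_valid = sum(.data$valid, na.rm = TRUE),
      .groups = "drop"
    )
  means <- features |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(num_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  out <- dplyr::left_join(counts, means, by = keys)
  center_relative_speed(out)
}

#' Fit the per-parameter linear mixed-effects model
#'
#' Fits `response ~ carry_mode * load + centered_relative_speed` with a
#' participant random intercept, a participant random slope on the
#' covariate, and a participant-by-condition random intercept (inducing
#' compound symmetry between a condition's repeated trials). Denominator
#' degrees of freedom use the Satterthwaite approximation; fixed-effect
#' F tests are Type III with sum contrasts. Singular or non-converging
#' fits are automatically refitted down a ladder (drop the random slope,
#' then the condition component, then participant intercept only) and the
#' step taken is reported.
#'
#' @param trial_table Trial-level tibble from [aggregate_trials()] or
#'   [simulate_trial_table()].
#' @param response Response column name (one of [gait_parameters()], or
#'   `"y"` for simulated tables).
#' @return A `gait_lmm` object: list with `fit` (lmerModLmerTest or lm),
#'   `anova` (term F table), `response`, `formula_used`, `convergence`.
#' @export
fit_gait_lmm <- function(trial_table, response) {
  stopifnot(response %in% names(trial_table))
  d <- trial_table
  d$.y <- d[[response]]
  d <- d[is.finite(d$.y), ]
  if (length(unique(d$participant)) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  d$carry_mode <- droplevels(factor(d$carry_mode))
  d$load <- droplevels(factor(d$load))
  d$cond <- interaction(d$carry_mode, d$load, drop = TRUE)

  if (var(d$.y) < .Machine$double.eps) {
    # constant response: degenerate model, report zero F without fitting
    an <- tibble::tibble(
      term = c("carry_mode", "load", "carry_mode:load",
        "centered_relative_speed"),
      F = 0, df1 = NA_real_, df2 = NA_real_, p = NA_real_
    )
    return(structure(
      list(
        fit = NULL, anova = an, response = response,
        formula_used = NULL, convergence = "degenerate (constant response)"
      ),
      class = "gait_lmm"
    ))
  }

  forms <- c(
    ".y ~ carry_mode * load + centered_relative_speed + (1 | participant) + (0 + centered_relative_speed | participant) + (1 | participant:cond)",
    ".y ~ carry_mode * load + centered_relative_speed + (1 | participant) + (1 | participant:cond)",
    ".y ~ carry_mode * load + centered_relative_speed + (1 | participant)"
  )
  labels <- c(
    "full (participant intercept + covariate slope + condition component)",
    "reduced (no covariate slope)",
    "participant intercept only"
  )
  contr <- list(carry_mode = "contr.sum", load = "contr.sum")
  fit <- NULL
  convergence <- NA_character_
  for (k in seq_along(forms)) {
    cand <- suppressWarnings(suppressMessages(try(
      lmerTest::lmer(stats::as.formula(forms[k]),
        data = d, contrasts = contr, REML = TRUE,
        control = lme4::lmerControl(
          check.conv.singular = "ignore",
          calc.derivs = FALSE
        )
      ),
      silent = TRUE
    )))
    if (inherits(cand, "try-error")) next
    if (!lme4::isSingular(cand, tol = 1e-5) || k == length(forms)) {
      fit <- cand
      convergence <- labels[k]
      if (lme4::isSingular(cand, tol = 1e-5)) {
        convergence <- paste0(labels[k], "; singular")
      }
      break
    }
    if (is.null(fit)) {
      fit <- cand
      convergence <- paste0(labels[k], "; singular")
    }
  }
  if (is.null(fit)) {
    stop("mixed model could not be fitted for response '", response, "'",
      call. = FALSE
    )
  }
  an_raw <- suppressMessages(stats::anova(fit, type = 3))
  an <- tibble::tibble(
    term = rownames(an_raw),
    F = an_raw$`F value`,
    df1 = an_raw$NumDF,
    df2 = an_raw$DenDF,
    p = an_raw$`Pr(>F)`
  )
  structure(
    list(
      fit = fit, anova = an, response = response,
      formula_used = forms[match(sub(";.*", "", convergence), labels)],
      convergence = convergence
    ),
    class = "gait_lmm"
  )
}

#' @export
print.gait_lmm <- function(x, ...) {
  cat("<gait_lmm> response:", x$response, "\n")
  cat("  model:", x$convergence, "\n")
  print(as.data.frame(x$anova), digits = 4)
  invisible(x)
}

#' Tidy the fixed-effect F tests of a fitted gait model
#'
#' @param x A `gait_lmm` object.
#' @param ... Unused.
#' @return Tibble with `term`, `F`, `df1`, `df2`, `p`.
#' @method tidy gait_lmm
#' @export
tidy.gait_lmm <- function(x, ...) x$anova

#' One-line model summary of a fitted gait model
#'
#' @param x A `gait_lmm` object.
#' @param ... Unused.
#' @return One-row tibble: response, observations, participants, sigma,
#'   REML criterion, convergence note.
#' @method glance gait_lmm
#' @export
glance.gait_lmm <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(
      response = x$response, nobs = NA_integer_, n_participants = NA_integer_,
      sigma = NA_real_, REML = NA_real_, convergence = x$convergence
    ))
  }
  fr <- stats::model.frame(x$fit)
  tibble::tibble(
    response = x$response,
    nobs = nrow(fr),
    n_participants = length(unique(fr$participant)),
    sigma = stats::sigma(x$fit),
    REML = as.numeric(lme4::getME(x$fit, "devcomp")$cmp["REML"]),
    convergence = x$convergence
  )
}

#' Estimated marginal means by carrying mode and load level
#'
#' EMMs for each mode-by-load cell evaluated at the average value of the
#' centered relative-speed covariate, with Satterthwaite-based standard
#' errors. The empty-handed reference is shared between modes, so a pooled
#' `no_load` row (modes averaged at the no-load level) is appended.
#'
#' @param x A `gait_lmm` object.
#' @return An `emm_table` tibble: `carry_mode`, `load`, `emmean`, `se`,
#'   `df`, `lower`, `upper`, plus the pooled no-load row.
#' @export
emm_table <- function(x) {
  stopifnot(inherits(x, "gait_lmm"))
  if (is.null(x$fit)) stop("degenerate fit: no EMMs available", call. = FALSE)
  em <- suppressMessages(emmeans::emmeans(x$fit, ~ carry_mode * load,
    lmer.df = "satterthwaite"
  ))
  s <- as.data.frame(em)
  out <- tibble::tibble(
    carry_mode = as.character(s$carry_mode),
    load = as.character(s$load),
    emmean = s$emmean, se = s$SE, df = s$df,
    lower = s$lower.CL, upper = s$upper.CL
  )
  if ("NL" %in% out$load) {
    # pooled no-load row: modes averaged at the shared reference level
    pooled <- as.data.frame(suppressMessages(emmeans::emmeans(x$fit, ~load,
      lmer.df = "satterthwaite"
    )))
    nl <- pooled[pooled$load == "NL", ]
    out <- dplyr::bind_rows(out, tibble::tibble(
      carry_mode = "pooled", load = "NL",
      emmean = nl$emmean, se = nl$SE, df = nl$df,
      lower = nl$lower.CL, upper = nl$upper.CL
    ))
  }
  attr(out, "response") <- x$response
  class(out) <- c("emm_table", class(out))
  out
}

#' Bonferroni-adjusted pairwise contrasts
#'
#' Pairwise comparisons between carrying modes at each load level and
#' between load levels within each carrying mode, Bonferroni-adjusted
#' within each family: mode-within-load forms one single-comparison family
#' per load level, load-within-mode one six-comparison family per mode
#' (adjusted p = min(1, 6 x raw p)).
#'
#' @param x A `gait_lmm` object.
#' @return Tibble with `family`, `by`, `contrast`, `estimate`, `se`, `df`,
#'   `t`, `p_raw`, `p_adj`.
#' @export
bonferroni_contrasts <- function(x) {
  stopifnot(inherits(x, "gait_lmm"))
  if (is.null(x$fit)) {
    stop("degenerate fit: no contrasts available", call. = FALSE)
  }
  em <- suppressMessages(emmeans::emmeans(x$fit, ~ carry_mode * load,
    lmer.df = "satterthwaite"
  ))
  mode_by_load <- as.data.frame(emmeans::contrast(
    em, "pairwise",
    by = "load", adjust = "bonferroni"
  ))
  load_by_mode <- as.data.frame(emmeans::contrast(
    em, "pairwise",
    by = "carry_mode", adjust = "bonferroni"
  ))
  shape <- function(d, family, by_col) {
    tibble::tibble(
      family = family,
      by = as.character(d[[by_col]]),
      contrast = as.character(d$contrast),
      estimate = d$estimate, se = d$SE, df = d$df,
      t = d$t.ratio, p_adj = d$p.value
    )
  }
  out <- dplyr::bind_rows(
    shape(mode_by_load, "mode_within_load", "load"),
    shape(load_by_mode, "load_within_mode", "carry_mode")
  )
  m <- ifelse(out$family == "mode_within_load", 1, 6)
  out$p_raw <- 2 * stats::pt(-abs(out$t), out$df)
  out$p_adj <- pmin(1, m * out$p_raw)
  out[, c(
    "family", "by", "contrast", "estimate", "se", "df", "t",
    "p_raw", "p_adj"
  )]
}

#' Analyze every gait parameter of a feature table
#'
#' Aggregates cycles to trials, then for each of the nine sway and
#' coordination parameters fits the mixed model and extracts the F table,
#' EMMs and Bonferroni contrasts.
#'
#' @param features Per-cycle feature tibble.
#' @param responses Parameter columns to analyze (default all nine).
#' @return List with `trials`, `models` (named list of `gait_lmm`),
#'   `anova` (stacked F tables), `emm` (stacked EMM tables), `contrasts`
#'   (stacked contrast tables).
#' @export
analyze_gait <- function(features, responses = gait_parameters()) {
  trials <- aggregate_trials(features)
  responses <- intersect(responses, names(trials))
  models <- lapply(responses, function(r) fit_gait_lmm(trials, r))
  names(models) <- responses
  anova_tab <- purrr::map_dfr(
    models,
    ~ dplyr::mutate(tidy.gait_lmm(.x), response = .x$response)
  )
  emm_tab <- purrr::map_dfr(models, function(m) {
    if (is.null(m$fit)) {
      return(NULL)
    }
    dplyr::mutate(tibble::as_tibble(emm_table(m)), response = m$response)
  })
  ctr_tab <- purrr::map_dfr(models, function(m) {
    if (is.null(m$fit)) {
      return(NULL)
    }
    dplyr::mutate(bonferroni_contrasts(m), response = m$response)
  })
  list(
    trials = trials, models = models,
    anova = anova_tab, emm = emm_tab, contrasts = ctr_tab
  )
}

#' Pearson correlations among the sway and coordination parameters
#'
#' @param trial_table Trial-level tibble ([aggregate_trials()]).
#' @param params Parameter columns (default the nine sway/coordination
#'   parameters present).
#' @return List with `matrix` (symmetric correlation matrix, unit
#'   diagonal, `NA` for zero-variance columns) and `tidy` (long tibble of
#'   the upper triangle).
#' @export
parameter_correlations <- function(trial_table,
                                   params = gait_parameters()) {
  params <- intersect(params, names(trial_table))
  stopifnot(length(params) >= 2, nrow(trial_table) >= 3)
  m <- as.matrix(trial_table[params])
  zero_var <- apply(m, 2, function(col) var(col, na.rm = TRUE)) <
    .Machine$double.eps
  cm <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  cm[zero_var, ] <- NA_real_
  cm[, zero_var] <- NA_real_
  diag(cm) <- ifelse(zero_var, NA_real_, 1)
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  tidy <- tibble::tibble(
    param1 = params[idx[, 1]],
    param2 = params[idx[, 2]],
    r = cm[idx]
  )
  list(matrix = cm, tidy = tidy)
}

#' Residual diagnostics for a fitted gait model
#'
#' Residual table plus normality (Shapiro-Wilk) and per-cell
#' homogeneity-of-variance summaries, the tabular counterparts of Q-Q and
#' residual box plots.
#'
#' @param x A `gait_lmm` object.
#' @return List with `residuals` (tibble: fitted, residual, keys),
#'   `normality` (Shapiro-Wilk W and p) and `variances` (per mode-by-load
#'   residual SD).
#' @export
model_diagnostics <- function(x) {
  stopifnot(inherits(x, "gait_lmm"))
  if (is.null(x$fit)) stop("degenerate fit: no diagnostics", call. = FALSE)
  fr <- stats::model.frame(x$fit)
  res <- tibble::tibble(
    participant = fr$participant,
    carry_mode = fr$carry_mode,
    load = fr$load,
    fitted = stats::fitted(x$fit),
    residual = stats::resid(x$fit)
  )
  sw <- tryCatch(
    shapiro.test(res$residual),
    error = function(e) list(statistic = NA_real_, p.value = NA_real_)
  )
  vars <- res |>
    dplyr::group_by(.data$carry_mode, .data$load) |>
    dplyr::summarise(
      n = dplyr::n(), sd_residual = sd(.data$residual), .groups = "drop"
    )
  list(
    residuals = res,
    normality = tibble::tibble(
      W = unname(sw$statistic), p = unname(sw$p.value)
    ),
    variances = vars
  )
}
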