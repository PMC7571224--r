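test_that("trial aggregation averages cycles and propagates flags", {
  f <- tibble::tibble(
    participant = "P01", carry_mode = "side", load = "H", trial = 1L,
    cycle = 2:6,
    mrp_coronal = c(100, 110, 120, 100, 110),
    relative_speed = 1.1,
    valid = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  out <- aggregate_trials(f)
  expect_equal(nrow(out), 1)
  expect_equal(out$mrp_coronal, mean(c(100, 110, 120, 100))) # invalid dropped
  expect_equal(out$n_cycles, 5)
  expect_equal(out$n_cycles_valid, 4)

  # identical rows average to themselves
  f$valid <- TRUE
  f$mrp_coronal <- 107
  expect_equal(aggregate_trials(f)$mrp_coronal, 107)
})

test_that("EMMs equal cell means on a balanced design with orthogonal covariate", {
  set.seed(42)
  grid <- tidyr::expand_grid(
    participant = sprintf("P%02d", 1:6),
    carry_mode = factor(c("side", "anterior")),
    load = factor(c("NL", "L", "M", "H"), levels = c("NL", "L", "M", "H")),
    trial = 1:2
  )
  cell_mu <- c(NL = 100, L = 105, M = 112, H = 120)
  b0 <- rnorm(6, 0, 5)
  grid$centered_relative_speed <- rep(c(-0.05, 0.05), nrow(grid) / 2)
  grid$y <- cell_mu[as.character(grid$load)] +
    ifelse(grid$carry_mode == "side", 4, -4) +
    b0[match(grid$participant, unique(grid$participant))] +
    rnorm(nrow(grid), 0, 1)
  fit <- fit_gait_lmm(grid, "y")
  em <- emm_table(fit)
  obs <- grid |>
    dplyr::group_by(.data$carry_mode, .data$load) |>
    dplyr::summarise(mu = mean(.data$y), .groups = "drop")
  j <- dplyr::inner_join(
    dplyr::filter(em, .data$carry_mode != "pooled"),
    dplyr::mutate(obs,
      carry_mode = as.character(carry_mode), load = as.character(load)
    ),
    by = c("carry_mode", "load")
  )
  expect_equal(nrow(j), 8)
  expect_lt(max(abs(j$emmean - j$mu)), 1e-6)
})

test_that("Bonferroni adjustment is m * p capped at 1, monotone in raw p", {
  st <- simulate_trial_table(seed = 4)
  fit <- fit_gait_lmm(st, "y")
  ct <- bonferroni_contrasts(fit)
  lw <- dplyr::filter(ct, .data$family == "load_within_mode")
  expect_equal(lw$p_adj, pmin(1, 6 * lw$p_raw)) # 6 pairs of 4 load levels
  mw <- dplyr::filter(ct, .data$family == "mode_within_load")
  expect_equal(mw$p_adj, mw$p_raw) # single-comparison families
  expect_true(all(ct$p_adj >= ct$p_raw))
  expect_true(all(ct$p_adj <= 1))
  # arithmetic: m = 4 comparisons at raw p = 0.02 would adjust to 0.08
  expect_equal(min(1, 4 * 0.02), 0.08)
})

test_that("a constant response yields a degenerate report, not a crash", {
  st <- simulate_trial_table(seed = 1)
  st$y <- 5
  fit <- fit_gait_lmm(st, "y")
  expect_match(fit$convergence, "degenerate")
  expect_true(all(fit$anova$F == 0))
  expect_error(emm_table(fit), "degenerate")
})

test_that("injected mode effects are detected with high power", {
  eff <- 20 # deg shift on all side-carry cells
  cells <- setNames(
    rep(c(eff, 0), each = 4),
    paste(rep(c("side", "anterior"), each = 4), c("NL", "L", "M", "H"),
      sep = "."
    )
  )
  hits <- 0
  n_sim <- 100
  for (i in seq_len(n_sim)) {
    st <- simulate_trial_table(cell_means = cells, seed = 3000 + i)
    fit <- fit_gait_lmm(st, "y")
    p <- fit$anova$p[fit$anova$term == "carry_mode"]
    if (is.finite(p) && p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.8)
})

test_that("fixed-effect estimates recover injected offsets without bias", {
  eff <- 15
  cells <- setNames(
    rep(c(eff, 0), each = 4),
    paste(rep(c("side", "anterior"), each = 4), c("NL", "L", "M", "H"),
      sep = "."
    )
  )
  est <- vapply(1:40, function(i) {
    st <- simulate_trial_table(cell_means = cells, seed = 5000 + i)
    fit <- fit_gait_lmm(st, "y")
    em <- emm_table(fit)
    mean(em$emmean[em$carry_mode == "side"]) -
      mean(em$emmean[em$carry_mode == "anterior"])
  }, numeric(1))
  # Monte-Carlo error of the mean estimate
  expect_lt(abs(mean(est) - eff), 3 * sd(est) / sqrt(length(est)) + 0.5)
})

test_that("no-load EMM is invariant to the mode label of the reference trials", {
  st <- simulate_trial_table(seed = 77)
  fit <- fit_gait_lmm(st, "y")
  em <- emm_table(fit)
  pooled <- em$emmean[em$carry_mode == "pooled" & em$load == "NL"]
  # swap the mode labels of every no-load trial and refit
  st2 <- st
  nl <- st2$load == "NL"
  st2$carry_mode[nl] <- factor(
    ifelse(st2$carry_mode[nl] == "side", "anterior", "side"),
    levels = levels(st2$carry_mode)
  )
  em2 <- emm_table(fit_gait_lmm(st2, "y"))
  pooled2 <- em2$emmean[em2$carry_mode == "pooled" & em2$load == "NL"]
  expect_equal(pooled, pooled2, tolerance = 1e-6)
})

test_that("correlation matrix is symmetric with unit diagonal and NA zero-variance", {
  set.seed(9)
  tt <- tibble::tibble(
    rom_coronal_t6 = rnorm(30), rom_coronal_s1 = rnorm(30),
    mrp_coronal = rnorm(30), mrp_transverse = rep(1, 30) # zero variance
  )
  cors <- parameter_correlations(tt)
  m <- cors$matrix
  expect_true(isSymmetric(m))
  expect_equal(diag(m)[1:3], setNames(rep(1, 3), colnames(m)[1:3]))
  expect_true(all(is.na(m["mrp_transverse", ])))
  # near-deterministic linear relation approaches r = 1
  tt2 <- tibble::tibble(
    rom_coronal_t6 = rnorm(100),
    rom_coronal_s1 = NA_real_
  )
  tt2$rom_coronal_s1 <- 2 * tt2$rom_coronal_t6 + rnorm(100, 0, 1e-4)
  expect_gt(parameter_correlations(tt2)$matrix[1, 2], 0.999)
})

test_that("independent columns rarely correlate beyond 0.25 at n = 144", {
  over <- vapply(1:20, function(i) {
    set.seed(600 + i)
    a <- rnorm(144)
    b <- rnorm(144)
    abs(cor(a, b)) > 0.25
  }, logical(1))
  expect_lte(mean(over), 0.05 + 0.1) # 95% property with slack at 20 draws
})

test_that("model diagnostics expose residual normality and per-cell spread", {
  st <- simulate_trial_table(seed = 11)
  fit <- fit_gait_lmm(st, "y")
  d <- model_diagnostics(fit)
  expect_equal(nrow(d$residuals), nrow(st))
  expect_true(is.finite(d$normality$p))
  expect_equal(nrow(d$variances), 8)
  expect_s3_class(plot_gait_diagnostics(fit, "qq"), "ggplot")
  # tidy/glance methods
  expect_true(all(c("term", "F", "p") %in% names(tidy(fit))))
  expect_equal(glance(fit)$nobs, nrow(st))
})
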