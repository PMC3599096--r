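test_that("noiseless variable-risk data are recovered as a fixed point", {
  subs <- lapply(1:3, function(i) {
    gen_noiseless_subject(paste0("s", i),
                          iop = c(23, 58, 49, 62, 51, 57, 54) + i,
                          N0 = 1, r0 = 0.002, beta = 0.06)
  })
  fit <- fit_kinetic_model(lapply(subs, `[[`, "degen"),
                           lapply(subs, `[[`, "risk"),
                           model_spec("variable_risk", relative = TRUE))
  expect_lt(abs(fit$params[["r0"]] - 0.002) / 0.002, 1e-6)
  expect_lt(abs(fit$params[["beta"]] - 0.06) / 0.06, 1e-6)
  expect_lt(fit$RSS, 1e-14)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
})

test_that("constant observations drive the risk rate to its zero bound", {
  rs <- make_risk()
  flat <- degeneration_series("s1", "affected", "optic_nerve",
                              days = c(10, 40, 70, 100, 118),
                              values = rep(0.82, 5), kind = "relative")
  fit <- fit_kinetic_model(flat, rs, model_spec("constant_risk"))
  expect_lt(fit$params[["r0"]], 1e-8)
  expect_true("r0_at_zero_bound" %in% fit$flags)
})

test_that("too few observations for the free parameters is rejected up front", {
  sub <- gen_noiseless_subject(q_days = c(45, 100, 160))
  short <- degeneration_series("s1", "affected", "optic_nerve",
                               days = sub$degen$days[1:3],
                               values = sub$degen$values[1:3], kind = "relative")
  expect_error(
    fit_kinetic_model(short, sub$risk, model_spec("heterogeneity", relative = TRUE)),
    "insufficient", class = "neurokin_error")
})

test_that("R^2 follows its defining arithmetic", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(1.1, 2.0, 2.9)), 0.99)  # RSS = 0.02, TSS = 2
  expect_error(r_squared(c(2, 2, 2), c(2, 2, 2)), class = "neurokin_error")
})

test_that("fit p-value uses the mean-null F with level-adjusted df", {
  fake <- structure(
    list(spec = model_spec("variable_risk"), params = c(N0 = 1, r0 = 0.1, beta = 0.1),
         free = c("N0", "r0", "beta"), RSS = 0.02, TSS = 2, n = 12L, p_free = 3L,
         R2 = 0.99, fitted = NULL, observed = NULL),
    class = "fit_result")
  # F = ((2 - 0.02)/2)/(0.02/10) = 495 on (2, 10)
  oracle <- stats::integrate(stats::df, 495, Inf, df1 = 2, df2 = 10,
                             rel.tol = 1e-12)$value
  expect_equal(regression_pvalue(fake), 1.00000001755758e-10, tolerance = 1e-8)
  expect_equal(regression_pvalue(fake), oracle, tolerance = 1e-6)
  fake$RSS <- fake$TSS
  expect_equal(regression_pvalue(fake), 1)
  fake$RSS <- 0
  expect_equal(regression_pvalue(fake), 0)
})

test_that("F tail probabilities match the numeric-integration and t-distribution oracles", {
  expect_equal(f_tail_probability(0, 1, 10), 1)
  # analytic identity at df (1, k): P = 2 (1 - T_k(sqrt(F)))
  for (Fv in c(0.5, 4, 37.9)) {
    for (k in c(3, 9, 10)) {
      expect_equal(f_tail_probability(Fv, 1, k),
                   2 * (1 - stats::pt(sqrt(Fv), k)), tolerance = 1e-12)
    }
  }
  oracle <- stats::integrate(stats::df, 29.7, Inf, df1 = 1, df2 = 3,
                             rel.tol = 1e-12)$value
  expect_equal(f_tail_probability(29.7, 1, 3), oracle, tolerance = 1e-10)
  expect_equal(f_tail_probability(29.7, 1, 3), 0.0121352394182511, tolerance = 1e-10)
  ps <- vapply(c(1, 5, 20, 50), f_tail_probability, numeric(1), df1 = 2, df2 = 8)
  expect_true(all(diff(ps) < 0))
})

test_that("nested F-test applies the extra-sum-of-squares formula and guards nesting", {
  sub <- gen_noiseless_subject(q_days = c(20, 45, 70, 100, 130, 160))
  mk_fit <- function(spec, rss) {
    f <- fit_kinetic_model(sub$degen, sub$risk, spec, opts = fit_options(multistart = 2))
    f$RSS <- rss  # fix RSS to the worked example's values
    f
  }
  red <- mk_fit(model_spec("constant_risk"), 2.0)       # p_free = 2 (N0, r0)
  ful <- mk_fit(model_spec("variable_risk"), 1.0)       # p_free = 3
  red$n <- ful$n <- 12L
  cmp <- nested_f_test(red, ful)
  expect_equal(cmp$F, 9.0)
  expect_equal(c(cmp$df1, cmp$df2), c(1L, 9L))
  expect_equal(cmp$p_value, f_tail_probability(9, 1, 9))

  same <- ful; same$RSS <- red$RSS
  cmp0 <- nested_f_test(red, same)
  expect_equal(cmp0$F, 0)
  expect_equal(cmp0$p_value, 1)

  worse <- ful; worse$RSS <- 2.5
  expect_warning(cmp_w <- nested_f_test(red, worse), "floor")
  expect_equal(cmp_w$F, 0)

  expect_error(nested_f_test(ful, red), "not nested", class = "neurokin_error")
  expect_error(nested_f_test(mk_fit(model_spec("constant_rate"), 1), ful),
               "not nested", class = "neurokin_error")
})

test_that("the printed headline model-selection statistic clears its significance bound", {
  p <- f_tail_probability(37.9, 1, 10)
  expect_equal(p, 0.000107430079493211, tolerance = 1e-10)
  expect_lt(p, 5e-4)
})

test_that("secondary linear coupling is recovered by least squares", {
  N_A <- c(1.0, 0.85, 0.62, 0.41, 0.33)
  fit <- fit_secondary_linear(N_A, 0.4 + 0.5 * N_A)
  expect_equal(fit$k_t, 0.5, tolerance = 1e-12)
  expect_equal(fit$N_B0, 0.4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_secondary_linear(rep(0.5, 5), rnorm(5)), "degenerate",
               class = "neurokin_error")
  expect_error(fit_secondary_linear(c(1, 2), c(1, 2)), class = "neurokin_error")
})

test_that("risk-based secondary fits recover exact parameters and flag flat series", {
  rs <- make_risk(days = c(0, 15, 40, 70, 100, 135, 160),
                  iop = c(23, 56, 49, 61, 52, 58, 54))
  q_days <- c(15, 40, 70, 100, 135, 160)
  R <- cumulative_risk(rs$days, query_days = q_days, p = rs$iop - 29,
                       r0 = 0.002, beta = 0.06)$R
  truth <- c(N_B0 = 0.3, A = 0.7)
  vals <- truth[["N_B0"]] + truth[["A"]] * exp(-R)
  degB <- degeneration_series("s1", "affected", "optic_radiation",
                              days = q_days, values = vals, kind = "relative")
  fit <- fit_secondary_risk(degB, rs)
  expect_equal(unname(fit$params[c("N_B0", "A", "r0", "beta")]),
               c(0.3, 0.7, 0.002, 0.06), tolerance = 1e-5)

  flat <- degeneration_series("s1", "affected", "optic_radiation",
                              days = q_days, values = rep(0.4, 6), kind = "relative")
  ffit <- fit_secondary_risk(flat, rs)
  expect_true("amplitude_near_zero_r0_unidentifiable" %in% ffit$flags)
})

test_that("pooled fits are invariant to subject ordering", {
  arm <- gen_primary_arm(404)
  opts <- fit_options(multistart = 2)
  spec <- model_spec("variable_risk", relative = TRUE)
  f1 <- fit_kinetic_model(arm$degen, arm$risk, spec, opts = opts)
  f2 <- fit_kinetic_model(rev(arm$degen), rev(arm$risk), spec, opts = opts)
  expect_equal(f1$params, f2$params, tolerance = 1e-9)
  expect_equal(f1$RSS, f2$RSS, tolerance = 1e-12)
})

test_that("warm-started nested chains never increase RSS and order as expected", {
  study <- simulate_study(simulation_config(seed = 77))
  cmp <- compare_models(
    study, lapply(c("constant_risk", "variable_risk", "heterogeneity"),
                  model_spec, relative = TRUE),
    opts = fit_options(multistart = 4))
  rss <- vapply(cmp$fits, `[[`, numeric(1), "RSS")
  expect_true(all(diff(rss) <= 1e-12))
  expect_length(cmp$comparisons, 2L)
  # generated under variable risk: the middle model must beat constant risk
  expect_lt(cmp$comparisons[[1L]]$p_value, 0.05)
})

test_that("gamma estimates stuck at the boundary are flagged, not silently accepted", {
  # generate compressed decay (gamma = 2) but cap gamma below the truth: the
  # optimizer must run into the ceiling and the fit must say so
  rs <- make_risk(days = c(0, 15, 40, 70, 100, 135, 160),
                  iop = c(23, 56, 49, 61, 52, 58, 54))
  q_days <- c(15, 40, 70, 100, 135, 160)
  R <- cumulative_risk(rs$days, query_days = q_days, p = rs$iop - 29,
                       r0 = 0.004, beta = 0.05)$R
  deg <- degeneration_series("s1", "affected", "optic_nerve", days = q_days,
                             values = exp(-R^2), kind = "relative")
  fit <- fit_kinetic_model(deg, rs, model_spec("heterogeneity", relative = TRUE),
                           opts = fit_options(multistart = 4, upper = c(gamma = 1.5)))
  expect_equal(fit$params[["gamma"]], 1.5, tolerance = 1e-6)
  expect_true("gamma_at_boundary" %in% fit$flags)
})
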