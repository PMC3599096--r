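test_that("simulation is deterministic given the seed and leaves the RNG alone", {
  cfg <- simulation_config(seed = 11)
  a <- simulate_iop_course(cfg, 1)
  b <- simulate_iop_course(cfg, 1)
  expect_identical(a, b)
  c2 <- simulate_iop_course(cfg, 2)
  expect_false(identical(a$affected$iop, c2$affected$iop))

  set.seed(999)
  before <- .Random.seed
  invisible(simulate_study(simulation_config(seed = 5)))
  expect_identical(before, .Random.seed)

  s1 <- simulate_study(simulation_config(seed = 5))
  s2 <- simulate_study(simulation_config(seed = 5))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_risk_csv(s1$risk_series, p1)
  write_risk_csv(s2$risk_series, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical exports
})

test_that("generated pressures reproduce the configured group means", {
  cfg <- simulation_config(seed = 202)
  post_means <- numeric(100)
  fellow_all <- c()
  for (i in 1:100) {
    eyes <- simulate_iop_course(cfg, i)
    post <- eyes$affected$iop[-1L]
    post_means[i] <- mean(post)
    fellow_all <- c(fellow_all, eyes$fellow$iop)
    expect_true(all(eyes$affected$days == eyes$fellow$days))
    gaps <- diff(eyes$affected$days)
    expect_true(all(gaps > 0 & gaps <= 28 + 1e-9))
    # the last visit is pinned to the terminal day, so only the earlier gaps
    # are guaranteed to respect the lower bound
    if (length(gaps) > 1L) expect_true(all(head(gaps, -1L) >= 3 - 1e-9))
    expect_true(max(eyes$affected$days) >= 33 && max(eyes$affected$days) <= 168)
  }
  se <- sd(post_means) / sqrt(100)
  expect_lt(abs(mean(post_means) - 54.9), 2 * se + 0.5)
  expect_lt(abs(mean(fellow_all) - 23.2), 0.3)
  expect_lt(sd(fellow_all), 1.2)  # consistent with the 0.8 mmHg baseline sd
})

test_that("affected-eye pressure exceeds fellow-eye pressure at post-induction visits", {
  cfg <- simulation_config(seed = 303)
  diffs <- c()
  for (i in 1:50) {
    eyes <- simulate_iop_course(cfg, i)
    diffs <- c(diffs, eyes$affected$iop[-1L] - eyes$fellow$iop[-1L])
  }
  expect_gt(mean(diffs), 20)
  expect_gt(mean(diffs > 0), 0.95)
})

test_that("zero measurement noise reproduces the forward model exactly", {
  cfg <- simulation_config(seed = 7, fa_noise_sd = 0)
  eyes <- simulate_iop_course(cfg, 1)
  mri <- eyes$affected$days[eyes$affected$days >= 30][1:3]
  deg <- simulate_degeneration(eyes$affected, cfg, seed = 99, mri_days = mri)
  R <- cumulative_risk(eyes$affected$days, query_days = mri,
                       p = eyes$affected$iop - 29, r0 = 0.0019, beta = 0.057)
  expect_equal(deg$values, predict_survival(R, 1), tolerance = 1e-12)

  flat <- simulate_degeneration(eyes$fellow, cfg, seed = 99, mri_days = mri,
                                zero_risk = TRUE)
  expect_equal(flat$values, rep(1, 3))
})

test_that("control eyes carry no degeneration signal", {
  # pool several control-convention series; the fitted risk rate must sit at 0
  cfg <- simulation_config(seed = 59)
  degs <- list(); risks <- list()
  for (i in 1:4) {
    eyes <- simulate_iop_course(cfg, i, group = "glaucoma")
    risks[[i]] <- eyes$affected
    degs[[i]] <- simulate_degeneration(eyes$affected, cfg, seed = 100 + i,
                                       zero_risk = TRUE)
  }
  fit <- fit_kinetic_model(degs, risks, model_spec("constant_risk", relative = TRUE),
                           opts = fit_options(multistart = 2))
  expect_lt(fit$params[["r0"]], 5e-4)
})

test_that("a default study has the documented structure", {
  study <- simulate_study(simulation_config(seed = 321))
  groups <- vapply(study$risk_series, function(r) r$group, character(1))
  ids <- vapply(study$risk_series, function(r) r$subject_id, character(1))
  expect_equal(length(unique(ids[groups == "glaucoma"])), 5L)
  expect_equal(length(unique(ids[groups == "control"])), 3L)
  kinds <- vapply(study$degen_series, function(d) d$kind, character(1))
  regions <- vapply(study$degen_series, function(d) d$region, character(1))
  expect_true(any(kinds == "quantitative") && any(kinds == "relative"))
  expect_true(any(regions == "optic_radiation"))
  expect_equal(nrow(study$histology), 16L)
  # every quantitative value respects the FA range
  for (d in study$degen_series) {
    if (d$kind == "quantitative") expect_true(all(d$values > 0 & d$values <= 1))
  }
})

test_that("terminal relative FA tracks exp(-R) within the noise envelope", {
  cfg <- simulation_config(seed = 888)
  for (i in 1:5) {
    eyes <- simulate_iop_course(cfg, i)
    deg <- simulate_degeneration(eyes$affected, cfg, seed = 500 + i)
    R <- cumulative_risk(eyes$affected$days, query_days = deg$days,
                         p = eyes$affected$iop - 29, r0 = 0.0019, beta = 0.057)
    expect_lt(max(abs(deg$values - predict_survival(R, 1))),
              5 * cfg$fa_noise_sd / sqrt(3))
  }
})

test_that("histology generation is monotone without noise and near the target correlation with it", {
  fa <- data.frame(subject_id = paste0("s", 1:10),
                   eye = rep(c("affected", "fellow"), 5),
                   fa = seq(0.25, 0.75, length.out = 10))
  noiseless <- simulate_histology(fa, histology_config(noise_sd = 0,
                                                       axon_ratio_noise_sd = 0), seed = 1)
  expect_equal(cor(noiseless$fa, noiseless$nf_density, method = "spearman"), 1)

  expect_error(histology_config(slope = 0), class = "neurokin_error")

  # Monte-Carlo: with the default noise, Pearson r across many nerves sits
  # near the configured target level
  rs <- vapply(1:40, function(s) {
    fa2 <- data.frame(subject_id = paste0("s", 1:16),
                      eye = rep(c("affected", "fellow"), 8),
                      fa = withr::with_seed(2000 + s, runif(16, 0.25, 0.75)))
    h <- simulate_histology(fa2, histology_config(), seed = 3000 + s)
    cor(h$fa, h$nf_density)
  }, numeric(1))
  expect_gt(mean(rs), 0.80)
  expect_lt(mean(rs), 0.97)
})

test_that("an end-to-end default study recovers the generative kinetics", {
  study <- simulate_study(simulation_config(seed = 2024))
  cmp <- compare_models(study, list(model_spec("variable_risk", relative = TRUE)),
                        opts = fit_options(multistart = 4))
  fit <- cmp$fits$variable_risk
  expect_lt(abs(fit$params[["r0"]] - 0.0019) / 0.0019, 0.5)
  expect_lt(abs(fit$params[["beta"]] - 0.057) / 0.057, 0.5)
  expect_gt(fit$R2, 0.8)
})

test_that("parameter estimates track jittered ground truth across studies", {
  n_rep <- 40
  true_b <- withr::with_seed(4242, runif(n_rep, 0.03, 0.09))
  true_r <- withr::with_seed(4243, 0.0019 * exp(runif(n_rep, -0.7, 0.7)))
  est <- t(vapply(seq_len(n_rep), function(k) {
    arm <- gen_primary_arm(6000 + k,
                           true_params = c(N0 = 1, r0 = true_r[k], beta = true_b[k]))
    fit <- fit_kinetic_model(arm$degen, arm$risk,
                             model_spec("variable_risk", relative = TRUE),
                             opts = fit_options(multistart = 2))
    fit$params[c("r0", "beta")]
  }, numeric(2)))
  expect_gt(cor(est[, "r0"], true_r), 0.8)
  expect_gt(cor(est[, "beta"], true_b), 0.8)
})
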