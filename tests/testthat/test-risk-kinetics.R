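test_that("excess pressure subtracts the threshold with optional clamping", {
  rs <- risk_series("s1", "glaucoma", "affected", c(0, 40), c(23.2, 54.9))
  expect_equal(excess_pressure(rs, excess_risk_config()), c(-5.8, 25.9))
  expect_equal(excess_pressure(rs, excess_risk_config(clamp_negative = TRUE)),
               c(0, 25.9))
  at_thresh <- risk_series("s1", "glaucoma", "affected", c(0, 10), c(29, 29))
  expect_equal(excess_pressure(at_thresh, excess_risk_config()), c(0, 0))
})

test_that("risk function is r0 exp(beta p) and collapses to constant risk at beta 0", {
  p <- c(-5, 0, 10, 25.9)
  expect_equal(risk_function(p, r0 = 0.003, beta = 0), rep(0.003, 4))
  expect_equal(risk_function(0, r0 = 0.003, beta = 0.1), 0.003)
  # scalar arithmetic oracle at the headline relative-data parameters
  expect_equal(risk_function(25.9, r0 = 0.0019, beta = 0.057),
               0.0083157714476656, tolerance = 1e-12)
  expect_error(risk_function(30, r0 = 1, beta = 30), class = "neurokin_numeric_error")
})

test_that("multi-risk profile reduces to the single-factor law and composes exponents", {
  days <- c(0, 10, 20)
  p1 <- c(0, 5, 10)
  prof1 <- multi_risk_profile(days, betas = 0.05, covariates = list(p1))
  expect_equal(multi_risk_function(prof1, r0 = 0.002),
               risk_function(p1, r0 = 0.002, beta = 0.05))
  prof0 <- multi_risk_profile(days, betas = c(0, 0), covariates = list(p1, p1 * 2))
  expect_equal(multi_risk_function(prof0, r0 = 0.002), rep(0.002, 3))
  prof2 <- multi_risk_profile(0, betas = c(0.1, 0.2), covariates = list(10, 5))
  expect_equal(multi_risk_function(prof2, r0 = 0.001), 0.00738905609893065,
               tolerance = 1e-12)
  expect_error(multi_risk_profile(days, betas = c(0.1, 0.2),
                                  covariates = list(p1, c(1, 2))),
               class = "neurokin_error")
})

test_that("trapezoid cumulative risk matches simple integrands and refuses extrapolation", {
  curve <- cumulative_risk(c(0, 10, 20), query_days = c(0, 20), r = rep(0.01, 3))
  expect_equal(curve$R, c(0, 0.2))
  ramp <- cumulative_risk(c(0, 10), query_days = 10, r = c(0, 0.02))
  expect_equal(ramp$R, 0.1)
  expect_error(cumulative_risk(c(0, 10), query_days = 11, r = c(0, 0.02)),
               "extrapolate", class = "neurokin_error")
})

test_that("cumulative risk converges at O(h^2) to the closed form for linear pressure", {
  # p(t) = t  =>  R(T) = r0 (exp(beta T) - 1)/beta
  r0 <- 0.001; beta <- 0.05; T <- 100
  exact <- r0 * (exp(beta * T) - 1) / beta
  expect_equal(exact, 2.94826318205153, tolerance = 1e-12)
  errs <- vapply(c(1, 0.5, 0.25), function(h) {
    days <- seq(0, T, by = h)
    got <- cumulative_risk(days, query_days = T, p = days, r0 = r0, beta = beta)$R
    abs(got - exact) / exact
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1L]
  expect_true(all(ratios > 3.5 & ratios < 4.5))  # halving the step quarters the error
  days <- seq(0, T, by = 0.01)
  fine <- cumulative_risk(days, query_days = T, p = days, r0 = r0, beta = beta)$R
  expect_lt(abs(fine - exact) / exact, 1e-6)
})

test_that("cumulative risk is additive over subintervals on a shared grid", {
  days <- c(0, 7, 19, 40, 66, 90)
  p <- c(-6, 20, 31, 15, 27, 22)
  R <- cumulative_risk(days, query_days = days, p = p, r0 = 0.002, beta = 0.06)$R
  for (j in 2:5) {
    left <- cumulative_risk(days, query_days = days[j], p = p,
                            r0 = 0.002, beta = 0.06)$R
    # restart integration at days[j] on the tail grid
    tail_R <- cumulative_risk(days[j:6], query_days = days[6], p = p[j:6],
                              r0 = 0.002, beta = 0.06)$R
    expect_equal(left + tail_R, R[6], tolerance = 1e-12)
  }
  expect_true(all(diff(R) >= 0))
})

test_that("clamped sub-threshold pressure with zero baseline risk gives zero cumulative risk", {
  days <- c(0, 30, 80)
  iop <- c(22, 24, 23)  # all below the 29 mmHg threshold
  p <- pmax(iop - 29, 0)
  R <- cumulative_risk(days, query_days = days, p = p, r0 = 0, beta = 0.06)$R
  expect_equal(R, rep(0, 3))
})

test_that("forward predictions honor the analytic identities", {
  expect_equal(predict_constant_rate(0, N0 = 0.8, r0 = 0.01), 0.8)
  expect_equal(predict_constant_rate(c(10, 50), N0 = 0.8, r0 = 0), c(0.8, 0.8))
  expect_equal(predict_constant_rate(100, N0 = 0.64, r0 = 0.0024), 0.40)

  expect_equal(predict_survival(0, N0 = 0.9), 0.9)
  expect_equal(predict_survival(log(2), N0 = 1), 0.5)
  expect_equal(predict_survival(1, N0 = 0.73), 0.268551992055153, tolerance = 1e-12)

  expect_equal(predict_heterogeneity(4, N0 = 1, gamma = 0.5), exp(-2))
  expect_equal(predict_heterogeneity(0.5, N0 = 1, gamma = 2), exp(-0.25))
  expect_error(predict_heterogeneity(-0.1, N0 = 1, gamma = 1), class = "neurokin_error")
})

test_that("beta = 0 and gamma = 1 collapse the model hierarchy exactly", {
  days <- c(0, 12, 30, 55, 81, 100)
  iop <- c(23, 51, 60, 47, 58, 53)
  p <- iop - 29
  R_var <- cumulative_risk(days, query_days = days, p = p, r0 = 0.002, beta = 0)$R
  # bit-identical to integrating the constant risk r0 through the same rule,
  # and equal (to rounding) to the analytic line
  expect_identical(R_var, cumulative_risk(days, query_days = days,
                                          r = rep(0.002, 6))$R)
  expect_equal(R_var, 0.002 * (days - days[1L]), tolerance = 1e-13)
  Rq <- cumulative_risk(days, query_days = days, p = p, r0 = 0.002, beta = 0.06)
  expect_identical(predict_heterogeneity(Rq, N0 = 0.73, gamma = 1),
                   predict_survival(Rq, N0 = 0.73))
})

test_that("survival-type predictions are nonincreasing in R and bounded in (0, N0]", {
  for (s in 1:5) {
    R <- withr::with_seed(s, cumsum(runif(8, 0, 0.5)))
    R <- c(0, R)
    for (g in c(0.5, 1, 2)) {
      N <- predict_heterogeneity(R, N0 = 0.9, gamma = g)
      expect_true(all(diff(N) <= 0))
      expect_true(all(N > 0 & N <= 0.9))
    }
  }
})

test_that("secondary coupling is the affine map approaching the plateau", {
  cp <- secondary_coupling(k_t = 0.5, N_B0 = 0.4)
  expect_equal(predict_secondary(c(1.0, 0.5), cp), c(0.9, 0.65))
  expect_equal(predict_secondary(c(0.3, 0.9), secondary_coupling(0, 0.4, A = 0)),
               c(0.4, 0.4))
  # composition with the survival law: N_B(t) = N_B0 + k_t N_A0 exp(-R)
  R <- c(0, 0.4, 1.3)
  N_A <- predict_survival(R, N0 = 0.8)
  expect_equal(predict_secondary(N_A, cp), 0.4 + 0.5 * 0.8 * exp(-R))
})
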