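# Kinetic laws of risk-based neurodegeneration.
#
# The core model: the biomarker of neuronal/axonal integrity N(t) obeys
#   dN/dt = -r(t) N(t)  =>  N(t) = N0 exp(-R(t)),  R(t) = int r(s) ds,
# with instantaneous risk r(t) = r0 exp(beta p(t)) driven by the excess of
# the pathogenic biomarker p(t) above a threshold. R(t) is accumulated by
# the trapezoid rule over the irregular measurement grid.

#' Excess-pressure risk configuration
#'
#' Configures how the pathogenic biomarker is converted to an excess-risk
#' covariate p(t) = IOP(t) - threshold. The default threshold of 29 mmHg is
#' the 95% upper confidence limit of IOP in a normal eye. By default p(t) is
#' not clamped at zero: sub-threshold pressures lower (but never negate) the
#' risk through the exponential. `clamp_negative = TRUE` floors p at 0.
#'
#' @param threshold Threshold pressure theta in mmHg (> 0, default 29).
#' @param clamp_negative Logical; floor p(t) at 0 (default `FALSE`).
#' @return An object of class `excess_risk_config`.
#' @export
excess_risk_config <- function(threshold = 29, clamp_negative = FALSE) {
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0) stop_nk("'threshold' must be > 0 (mmHg)")
  if (!is.logical(clamp_negative) || length(clamp_negative) != 1L || is.na(clamp_negative)) {
    stop_nk("'clamp_negative' must be TRUE or FALSE")
  }
  structure(list(threshold = threshold, clamp_negative = clamp_negative),
            class = "excess_risk_config")
}

#' Excess pressure p(t) above the risk threshold
#'
#' Computes p_i = IOP_i - threshold for each measurement of a [risk_series],
#' optionally clamped at zero.
#'
#' @param iop A [risk_series].
#' @param cfg An [excess_risk_config].
#' @return Numeric vector of excess pressures (mmHg), one per measurement.
#' @examples
#' rs <- risk_series("s1", "glaucoma", "affected", c(0, 40), c(23.2, 54.9))
#' excess_pressure(rs, excess_risk_config())  # -5.8, 25.9
#' @export
excess_pressure <- function(iop, cfg = excess_risk_config()) {
  if (!inherits(iop, "risk_series")) stop_nk("'iop' must be a risk_series")
  if (!inherits(cfg, "excess_risk_config")) stop_nk("'cfg' must be an excess_risk_config")
  p <- iop$iop - cfg$threshold
  if (cfg$clamp_negative) p <- pmax(p, 0)
  p
}

# beta * p beyond this would overflow exp(); error rather than return Inf.
.EXP_OVERFLOW <- 700

#' Instantaneous risk r(t) = r0 exp(beta p(t))
#'
#' The time-variable risk function. With `beta = 0` it reduces exactly to the
#' constant risk r(t) = r0 of the one-hit model.
#'
#' @param p_values Numeric vector of excess-pressure values (mmHg).
#' @param r0 Baseline risk rate (per day, >= 0).
#' @param beta Risk sensitivity (per mmHg).
#' @return Numeric vector of risk values (per day).
#' @export
risk_function <- function(p_values, r0, beta) {
  assert_scalar_number(r0, "r0")
  assert_scalar_number(beta, "beta")
  if (r0 < 0) stop_nk("'r0' must be >= 0")
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(!is.finite(p_values))) stop_nk("'p_values' must be finite")
  ex <- beta * p_values
  if (any(ex > .EXP_OVERFLOW)) {
    stop_nk("beta * p overflows exp(); risk would not be representable",
            class = "neurokin_numeric_error")
  }
  r0 * exp(ex)
}

#' Multi-risk-factor profile
#'
#' Bundles several risk covariates p_1(t), ..., p_n(t) sharing one day grid,
#' each with its own sensitivity beta_i, for the multiplicative multi-risk
#' generalization r(t) = r0 exp(sum_i beta_i p_i(t)). This form is virtually
#' equivalent to a Cox proportional-hazards model with time-dependent
#' covariates; the equivalence is documented, not implemented.
#'
#' @param days Shared day grid (strictly increasing).
#' @param betas Numeric vector of sensitivities, one per factor.
#' @param covariates List of numeric vectors, each the same length as `days`.
#' @return An object of class `multi_risk_profile`.
#' @export
multi_risk_profile <- function(days, betas, covariates) {
  days <- as.numeric(days)
  if (length(days) > 1L && any(diff(days) <= 0)) stop_nk("'days' must be strictly increasing")
  if (!is.list(covariates) || length(covariates) != length(betas)) {
    stop_nk("'covariates' must be a list with one series per beta")
  }
  for (p in covariates) {
    if (length(p) != length(days)) {
      stop_nk("all covariate series must share the profile's day grid")
    }
  }
  structure(list(days = days, betas = as.numeric(betas),
                 covariates = lapply(covariates, as.numeric)),
            class = "multi_risk_profile")
}

#' Instantaneous risk under multiple risk factors
#'
#' @param profile A [multi_risk_profile].
#' @param r0 Baseline risk rate (per day, >= 0).
#' @return Numeric vector of risk values on the profile's day grid.
#' @export
multi_risk_function <- function(profile, r0) {
  if (!inherits(profile, "multi_risk_profile")) stop_nk("'profile' must be a multi_risk_profile")
  assert_scalar_number(r0, "r0")
  if (r0 < 0) stop_nk("'r0' must be >= 0")
  ex <- rep(0, length(profile$days))
  for (j in seq_along(profile$betas)) {
    ex <- ex + profile$betas[j] * profile$covariates[[j]]
  }
  if (any(ex > .EXP_OVERFLOW)) {
    stop_nk("sum(beta_j * p_j) overflows exp()", class = "neurokin_numeric_error")
  }
  r0 * exp(ex)
}

#' Cumulative risk by the trapezoid rule
#'
#' Integrates the instantaneous risk over the irregular measurement grid and
#' evaluates the integral R(t) at the requested query days. Integration
#' starts at the first measurement day (R = 0 there); query days must fall
#' inside the measured span — the integral is never extrapolated.
#'
#' Two input forms are supported:
#' \itemize{
#'   \item `r`: risk values on `days`; inserted query days take linearly
#'     interpolated r. Used for generic integrands.
#'   \item `p` with `r0`, `beta`: excess-pressure values on `days`; inserted
#'     query days take linearly interpolated p, which is then exponentiated,
#'     r = r0 exp(beta p). This is the form used by all model fits: p is the
#'     measured quantity, and exponentiating its interpolant preserves
#'     positivity when pressure swings widely.
#' }
#'
#' @param days Measurement days, strictly increasing, length >= 2.
#' @param query_days Days at which to evaluate R (within the measured span).
#' @param r Optional risk values on `days`.
#' @param p Optional excess-pressure values on `days` (requires `r0`, `beta`).
#' @param r0,beta Risk-function parameters, used with `p`.
#' @return A [cumulative_risk_curve] over `query_days`.
#' @examples
#' cumulative_risk(c(0, 10, 20), query_days = 20, r = rep(0.01, 3))$R  # 0.2
#' @export
cumulative_risk <- function(days, query_days = days, r = NULL,
                            p = NULL, r0 = NULL, beta = NULL) {
  days <- as.numeric(days)
  query_days <- as.numeric(query_days)
  if (length(days) < 2L) stop_nk("need at least 2 measurement days to integrate")
  if (any(diff(days) <= 0)) stop_nk("'days' must be strictly increasing")
  if (length(query_days) == 0L) stop_nk("'query_days' must be non-empty")
  if (any(query_days < days[1L] - 1e-9) || any(query_days > days[length(days)] + 1e-9)) {
    stop_nk(sprintf("query days outside the measured span [%g, %g]; refusing to extrapolate",
                    days[1L], days[length(days)]))
  }
  if (is.null(r) == is.null(p)) {
    stop_nk("supply exactly one of 'r' or 'p' (with r0 and beta)")
  }
  grid <- sort(unique(c(days, query_days)))
  if (!is.null(p)) {
    assert_scalar_number(r0, "r0")
    assert_scalar_number(beta, "beta")
    p <- as.numeric(p)
    if (length(p) != length(days)) stop_nk("'p' must match 'days' in length")
    p_grid <- stats::approx(days, p, xout = grid)$y
    r_grid <- risk_function(p_grid, r0, beta)
  } else {
    r <- as.numeric(r)
    if (length(r) != length(days)) stop_nk("'r' must match 'days' in length")
    if (any(r < 0)) stop_nk("risk values must be >= 0")
    r_grid <- stats::approx(days, r, xout = grid)$y
  }
  R_grid <- trapz_cumulative(grid, r_grid)
  idx <- match(query_days, grid)
  cumulative_risk_curve(days = query_days, R = R_grid[idx])
}

#' Constant-rate (classical linear) decay prediction
#'
#' The classical accelerated-aging model N(t) = N0 - r0 t: loss proceeds at a
#' fixed number of units per day regardless of risk. No floor is applied —
#' predictions can go negative at long times, a known property of this model.
#'
#' @param days Numeric vector of days.
#' @param N0 Initial biomarker level.
#' @param r0 Loss rate (units per day, >= 0).
#' @return Numeric vector N(t).
#' @export
predict_constant_rate <- function(days, N0, r0) {
  assert_scalar_number(N0, "N0")
  assert_scalar_number(r0, "r0")
  N0 - r0 * as.numeric(days)
}

#' Risk-based exponential survival prediction
#'
#' N(t) = N0 exp(-R(t)): the integrity biomarker decays exponentially in
#' cumulative risk. Strictly positive, and nonincreasing whenever R is
#' nondecreasing.
#'
#' @param R A [cumulative_risk_curve], or a numeric vector of cumulative risk
#'   values.
#' @param N0 Initial biomarker level (> 0).
#' @return Numeric vector N(t).
#' @export
predict_survival <- function(R, N0) {
  assert_scalar_number(N0, "N0")
  if (N0 <= 0) stop_nk("'N0' must be > 0")
  Rv <- if (inherits(R, "cumulative_risk_curve")) R$R else as.numeric(R)
  if (anyNA(Rv) || any(!is.finite(Rv))) stop_nk("cumulative risk must be finite")
  N0 * exp(-Rv)
}

#' Heterogeneity (stretched-exponential / Weibull) prediction
#'
#' N(t) = N0 exp(-R(t)^gamma). For 0 < gamma < 1 the decay is stretched
#' (fast early loss of a vulnerable subpopulation, long tail); gamma = 1
#' reproduces [predict_survival] exactly; gamma > 1 gives sigmoidal
#' (compressed) decay. This is a Weibull-type survival form.
#'
#' @param R A [cumulative_risk_curve] or numeric vector of cumulative risk
#'   values (>= 0).
#' @param N0 Initial biomarker level (> 0).
#' @param gamma Shape parameter (> 0).
#' @return Numeric vector N(t).
#' @export
predict_heterogeneity <- function(R, N0, gamma) {
  assert_scalar_number(N0, "N0")
  assert_scalar_number(gamma, "gamma")
  if (N0 <= 0) stop_nk("'N0' must be > 0")
  if (gamma <= 0) stop_nk("'gamma' must be > 0")
  Rv <- if (inherits(R, "cumulative_risk_curve")) R$R else as.numeric(R)
  if (anyNA(Rv) || any(!is.finite(Rv))) stop_nk("cumulative risk must be finite")
  if (any(Rv < 0)) stop_nk("cumulative risk must be >= 0")
  N0 * exp(-Rv^gamma)
}

#' Secondary (transsynaptic) coupling parameters
#'
#' In transsynaptic degeneration a downstream region B loses integrity in
#' proportion to the loss in the primarily degenerating region A:
#' dN_B/dt = k_t dN_A/dt, which integrates to the affine law
#' N_B = N_B0 + k_t N_A. As N_A -> 0, N_B approaches the plateau N_B0.
#' For risk-based secondary fits the product A = k_t N_A0 collapses into a
#' single amplitude parameter.
#'
#' @param k_t Coupling slope (dimensionless).
#' @param N_B0 Plateau/intercept of the secondary region.
#' @param A Optional amplitude k_t * N_A0 (>= 0 for degenerative coupling);
#'   defaults to `k_t` (i.e. N_A0 = 1, the relative-biomarker convention).
#' @return An object of class `secondary_coupling`.
#' @export
secondary_coupling <- function(k_t, N_B0, A = k_t) {
  assert_scalar_number(k_t, "k_t")
  assert_scalar_number(N_B0, "N_B0")
  assert_scalar_number(A, "A")
  if (A < 0) stop_nk("'A' must be >= 0 for degenerative coupling")
  structure(list(k_t = k_t, N_B0 = N_B0, A = A), class = "secondary_coupling")
}

#' Secondary-degeneration prediction from primary loss
#'
#' N_B = N_B0 + k_t N_A: composing with [predict_survival] gives
#' N_B(t) = N_B0 + k_t N_A0 exp(-R(t)) — an exponential approach to the
#' plateau N_B0 along the same cumulative-risk abscissa as the primary
#' region.
#'
#' @param N_A Numeric vector of primary-region biomarker values.
#' @param coupling A [secondary_coupling].
#' @return Numeric vector N_B.
#' @export
predict_secondary <- function(N_A, coupling) {
  if (!inherits(coupling, "secondary_coupling")) stop_nk("'coupling' must be a secondary_coupling")
  coupling$N_B0 + coupling$k_t * as.numeric(N_A)
}
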