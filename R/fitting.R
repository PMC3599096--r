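# Pooled nonlinear least-squares estimation of the kinetic models and
# extra-sum-of-squares F-tests for nested model selection.
#
# All glaucomatous subjects share one parameter set; each subject's
# cumulative risk is recomputed from its own pressure series at every
# optimizer iterate (the risk integral depends on r0 and beta, so it cannot
# be precomputed — only the interpolated pressure grid can).

.PRIMARY_MODELS <- c("constant_rate", "constant_risk", "variable_risk", "heterogeneity")
.SECONDARY_MODELS <- c("secondary_linear", "secondary_risk")

#' Kinetic model specification
#'
#' Defines which kinetic law is fitted and which parameters are free:
#' \describe{
#'   \item{constant_rate}{N(t) = N0 - r0 t (classical linear loss).}
#'   \item{constant_risk}{N(t) = N0 exp(-r0 (t - t_first)) — the one-hit
#'     model; beta is fixed at 0.}
#'   \item{variable_risk}{N(t) = N0 exp(-R(t)) with
#'     r(t) = r0 exp(beta p(t)).}
#'   \item{heterogeneity}{N(t) = N0 exp(-R(t)^gamma) (stretched
#'     exponential / Weibull).}
#'   \item{secondary_linear}{N_B = N_B0 + k_t N_A (ordinary least squares).}
#'   \item{secondary_risk}{N_B(t) = N_B0 + A exp(-R(t)) with amplitude
#'     A = k_t N_A0; fix `beta = 0` for its constant-risk variant.}
#' }
#' The nesting relations constant_risk < variable_risk < heterogeneity (and
#' beta-fixed < beta-free for secondary_risk) are declared here and enforced
#' by [nested_f_test]. With `relative = TRUE` the level parameter N0 is fixed
#' at 1, the convention for affected/fellow ratio data.
#'
#' @param name Model name, one of the six above.
#' @param relative Logical; fix N0 = 1 (ratio data). Primary models only.
#' @param fixed Named list of additional parameters to hold fixed
#'   (e.g. `list(beta = 0)` for the constant-risk secondary variant).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("constant_rate", "constant_risk", "variable_risk",
                                "heterogeneity", "secondary_linear", "secondary_risk"),
                       relative = FALSE, fixed = list()) {
  name <- match.arg(name)
  params <- switch(name,
    constant_rate = c("N0", "r0"),
    constant_risk = c("N0", "r0", "beta"),
    variable_risk = c("N0", "r0", "beta"),
    heterogeneity = c("N0", "r0", "beta", "gamma"),
    secondary_linear = c("N_B0", "k_t"),
    secondary_risk = c("N_B0", "A", "r0", "beta")
  )
  family <- if (name %in% .PRIMARY_MODELS) "primary" else "secondary"
  fixed <- as.list(fixed)
  if (length(fixed) && (is.null(names(fixed)) || any(!nzchar(names(fixed))))) {
    stop_nk("'fixed' must be a named list")
  }
  if (length(fixed) && !all(names(fixed) %in% params)) {
    stop_nk(sprintf("fixed parameter(s) %s are not parameters of model '%s'",
                    paste(setdiff(names(fixed), params), collapse = ", "), name))
  }
  if (name == "constant_risk") fixed$beta <- 0
  if (isTRUE(relative)) {
    if (family != "primary") stop_nk("'relative' applies to primary models only")
    fixed$N0 <- 1
  }
  free <- setdiff(params, names(fixed))
  if (!length(free)) stop_nk("model has no free parameters")
  structure(
    list(name = name, family = family, params = params,
         free = free, fixed = fixed, relative = isTRUE(relative)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  fx <- if (length(x$fixed)) {
    paste(sprintf("%s=%g", names(x$fixed), unlist(x$fixed)), collapse = ", ")
  } else "none"
  cat(sprintf("<model_spec> %s; free: %s; fixed: %s\n",
              x$name, paste(x$free, collapse = ", "), fx))
  invisible(x)
}

# TRUE when `reduced` is nested in `full` (same family, same functional line,
# strictly fewer free parameters, shared fixed values equal). The
# constant-rate model is a different functional form and nests in nothing.
is_nested_spec <- function(reduced, full) {
  if (!inherits(reduced, "model_spec") || !inherits(full, "model_spec")) return(FALSE)
  if (reduced$family != full$family) return(FALSE)
  if (reduced$name == "constant_rate" || full$name == "constant_rate") return(FALSE)
  if (reduced$name == "secondary_linear" || full$name == "secondary_linear") return(FALSE)
  order_primary <- c(constant_risk = 1, variable_risk = 2, heterogeneity = 3)
  if (reduced$family == "primary") {
    if (order_primary[[reduced$name]] >= order_primary[[full$name]]) return(FALSE)
  }
  if (!all(reduced$free %in% full$free)) return(FALSE)
  if (length(reduced$free) >= length(full$free)) return(FALSE)
  shared_fixed <- intersect(names(reduced$fixed), names(full$fixed))
  for (nm in shared_fixed) {
    if (!isTRUE(all.equal(reduced$fixed[[nm]], full$fixed[[nm]]))) return(FALSE)
  }
  TRUE
}

#' Fitting options
#'
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances (> 0).
#' @param maxiter Maximum iterations per start.
#' @param multistart Number of optimizer starts: the first uses heuristic
#'   initial values, the rest jitter them. The cumulative-risk dependence on
#'   (r0, beta) makes the objective non-convex, so several starts are kept by
#'   default.
#' @param seed Integer seed for the multistart jitter (fits are deterministic
#'   given the data and this seed).
#' @param lower,upper Optional named numeric vectors overriding the default
#'   parameter bounds (N0 > 0, gamma in (0, 5], 0 <= r0 <= 1 per day,
#'   0 <= A <= 100).
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(ftol = 1e-12, ptol = 1e-12, maxiter = 400,
                        multistart = 8L, seed = 1L,
                        lower = NULL, upper = NULL) {
  if (!is_scalar_number(ftol) || ftol <= 0) stop_nk("'ftol' must be > 0")
  if (!is_scalar_number(ptol) || ptol <= 0) stop_nk("'ptol' must be > 0")
  structure(
    list(ftol = ftol, ptol = ptol, maxiter = as.integer(maxiter),
         multistart = max(1L, as.integer(multistart)), seed = as.integer(seed),
         lower = lower, upper = upper),
    class = "fit_options"
  )
}

# Default box bounds per parameter. The r0 and A ceilings keep the optimizer
# off the degenerate flat ridge (A -> Inf with r0 -> Inf predicts a constant):
# a baseline hazard of 1/day or an amplitude of 100 is far outside the
# chronic-degeneration regime the models describe.
default_bounds <- function(free, opts) {
  lower <- c(N0 = 1e-8, r0 = 0, beta = -Inf, gamma = 1e-6, N_B0 = 0, A = 0, k_t = -Inf)
  upper <- c(N0 = Inf, r0 = 1, beta = Inf, gamma = 5, N_B0 = Inf, A = 100, k_t = Inf)
  lo <- lower[free]; up <- upper[free]
  if (!is.null(opts$lower)) lo[names(opts$lower)] <- opts$lower
  if (!is.null(opts$upper)) up[names(opts$upper)] <- opts$upper
  list(lower = lo, upper = up)
}

# ---- pooled data assembly ---------------------------------------------------

as_series_list <- function(x, class) {
  if (inherits(x, class)) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, TRUE, class))) return(x)
  stop_nk(sprintf("expected a %s or a list of them", class))
}

# Precompute, per subject, the integration grid and interpolated excess
# pressure; both are parameter-independent, so the per-iterate work reduces
# to exponentiation + one cumulative trapezoid pass.
assemble_pooled <- function(degen, risk, cfg, need_risk = TRUE) {
  degen <- as_series_list(degen, "degeneration_series")
  risk <- as_series_list(risk, "risk_series")
  obs_subject <- character(0); obs_day <- numeric(0); obs_value <- numeric(0)
  for (d in degen) {
    obs_subject <- c(obs_subject, rep(d$subject_id, length(d$days)))
    obs_day <- c(obs_day, d$days)
    obs_value <- c(obs_value, d$values)
  }
  if (!length(obs_value)) stop_nk("no degeneration observations to fit")
  subjects <- unique(obs_subject)
  precomp <- list()
  for (sid in subjects) {
    q_days <- sort(unique(obs_day[obs_subject == sid]))
    entry <- list(q_days = q_days)
    if (need_risk) {
      rs <- find_risk_series(risk, sid, "affected")
      if (is.null(rs)) {
        stop_nk(sprintf("no affected-eye risk series for subject '%s'", sid))
      }
      if (length(rs$days) < 2L) {
        stop_nk(sprintf("risk series for subject '%s' has fewer than 2 measurements", sid))
      }
      if (min(q_days) < min(rs$days) - 1e-9 || max(q_days) > max(rs$days) + 1e-9) {
        stop_nk(sprintf("degeneration days for subject '%s' fall outside its risk series span [%g, %g]",
                        sid, min(rs$days), max(rs$days)))
      }
      p_meas <- excess_pressure(rs, cfg)
      grid <- sort(unique(c(rs$days, q_days)))
      entry$grid <- grid
      entry$p_grid <- stats::approx(rs$days, p_meas, xout = grid)$y
      entry$q_idx <- match(q_days, grid)
    }
    precomp[[sid]] <- entry
  }
  # map each observation to (subject, position within the subject's q_days)
  obs_pos <- integer(length(obs_day))
  for (i in seq_along(obs_day)) {
    obs_pos[i] <- match(obs_day[i], precomp[[obs_subject[i]]]$q_days)
  }
  list(subject = obs_subject, day = obs_day, value = obs_value,
       pos = obs_pos, precomp = precomp, subjects = subjects)
}

# Model predictions at the pooled observation points for one parameter set.
# The exponent is capped inside the optimizer loop so wild trial values of
# beta degrade the fit instead of overflowing.
predict_pooled <- function(pool, spec, params, cap_exponent = TRUE) {
  N_hat <- numeric(length(pool$value))
  if (spec$name == "constant_rate") {
    return(params[["N0"]] - params[["r0"]] * pool$day)
  }
  gamma <- if ("gamma" %in% names(params)) params[["gamma"]] else 1
  for (sid in pool$subjects) {
    pc <- pool$precomp[[sid]]
    ex <- params[["beta"]] * pc$p_grid
    if (cap_exponent) ex <- pmin(ex, 40)
    r_grid <- params[["r0"]] * exp(ex)
    Rq <- trapz_cumulative(pc$grid, r_grid)[pc$q_idx]
    pred <- if (spec$name == "secondary_risk") {
      params[["N_B0"]] + params[["A"]] * exp(-Rq)
    } else {
      params[["N0"]] * exp(-(Rq^gamma))
    }
    sel <- pool$subject == sid
    N_hat[sel] <- pred[pool$pos[sel]]
  }
  N_hat
}

# Heuristic initial values (the first multistart start).
heuristic_start <- function(pool, spec) {
  y <- pool$value
  t_rel <- pool$day - vapply(pool$subject, function(s) min(pool$precomp[[s]]$q_days), numeric(1))
  start <- list()
  if (spec$name == "secondary_risk") {
    start$N_B0 <- max(min(y) * 0.8, 1e-4)
    start$A <- max(max(y) - start$N_B0, 1e-3)
    ratio <- pmax((y - start$N_B0) / start$A, 1e-3)
    sl <- tryCatch(stats::coef(stats::lm(-log(ratio) ~ t_rel))[[2]], error = function(e) NA_real_)
    start$r0 <- if (is.finite(sl) && sl > 0) sl else 1e-3
    start$beta <- 0.01
  } else {
    N0 <- if ("N0" %in% names(spec$fixed)) spec$fixed$N0 else max(mean(y[t_rel == min(t_rel)]), max(y))
    start$N0 <- N0
    if (spec$name == "constant_rate") {
      sl <- tryCatch(stats::coef(stats::lm(y ~ pool$day))[[2]], error = function(e) NA_real_)
      start$r0 <- if (is.finite(sl) && sl < 0) -sl else 1e-3
    } else {
      ratio <- pmax(y / N0, 1e-6)
      sl <- tryCatch(stats::coef(stats::lm(-log(ratio) ~ t_rel))[[2]], error = function(e) NA_real_)
      start$r0 <- if (is.finite(sl) && sl > 0) sl else 1e-3
      start$beta <- 0.01
      start$gamma <- 1
    }
  }
  unlist(start)[spec$params]
}

# Jittered variants of a start vector (multiplicative for scale parameters,
# additive for the sensitivity beta).
jitter_start <- function(start) {
  out <- start
  for (nm in names(out)) {
    out[nm] <- switch(nm,
      beta = out[nm] + stats::rnorm(1, 0, 0.03),
      k_t = out[nm] + stats::rnorm(1, 0, 0.2),
      out[nm] * exp(stats::rnorm(1, 0, 0.5))
    )
  }
  out
}

clip_to_bounds <- function(par, lower, upper) {
  pmin(pmax(par, lower + ifelse(is.finite(lower), 1e-10, 0)),
       upper - ifelse(is.finite(upper), 1e-10, 0))
}

#' Pooled nonlinear least-squares fit of a kinetic model
#'
#' Minimizes the pooled residual sum of squares
#' sum_i (y_i - N(t_i; params))^2 across all supplied degeneration series,
#' with one shared parameter set; each subject's cumulative risk is
#' recomputed from its own pressure series at every optimizer iterate.
#' Bounded Levenberg-Marquardt with multistart; deterministic given the data
#' and `opts$seed`.
#'
#' @param degen A [degeneration_series] or list of them (the observations).
#' @param risk A [risk_series] or list of them; each degeneration subject
#'   needs an affected-eye risk series spanning its measurement days (not
#'   used by the constant-rate model).
#' @param spec A [model_spec].
#' @param cfg An [excess_risk_config].
#' @param opts A [fit_options].
#' @param extra_starts Optional list of named parameter vectors used as
#'   additional optimizer starts (used internally to warm-start a full model
#'   at a reduced model's optimum, which guarantees RSS monotonicity under
#'   nesting).
#' @return An object of class `fit_result` with elements `spec`, `params`
#'   (full named vector, free and fixed), `free`, `RSS`, `TSS`, `n`,
#'   `p_free`, `R2`, `p_value`, `fitted`, `observed`, `days`, `subject`,
#'   `flags` and `convergence`.
#' @export
fit_kinetic_model <- function(degen, risk, spec, cfg = excess_risk_config(),
                              opts = fit_options(), extra_starts = list()) {
  if (!inherits(spec, "model_spec")) stop_nk("'spec' must be a model_spec")
  if (spec$name == "secondary_linear") {
    stop_nk("use fit_secondary_linear() for the secondary_linear model")
  }
  if (!inherits(cfg, "excess_risk_config")) stop_nk("'cfg' must be an excess_risk_config")
  if (!inherits(opts, "fit_options")) stop_nk("'opts' must be a fit_options")
  pool <- assemble_pooled(degen, risk, cfg, need_risk = spec$name != "constant_rate")
  y <- pool$value
  n <- length(y)
  p_free <- length(spec$free)
  if (n < p_free + 2L) {
    stop_nk(sprintf("insufficient data: %d observations for %d free parameters (need at least %d)",
                    n, p_free, p_free + 2L),
            class = "neurokin_validation_error")
  }
  fixed <- unlist(spec$fixed)
  bounds <- default_bounds(spec$free, opts)

  resid_fn <- function(free_par) {
    params <- c(free_par, fixed)
    y - predict_pooled(pool, spec, params)
  }

  h0 <- heuristic_start(pool, spec)
  starts <- list(clip_to_bounds(h0[spec$free], bounds$lower, bounds$upper))
  for (st in extra_starts) {
    st <- unlist(st)
    if (all(spec$free %in% names(st))) {
      starts <- c(starts, list(clip_to_bounds(st[spec$free], bounds$lower, bounds$upper)))
    }
  }
  n_jitter <- max(0L, opts$multistart - 1L)
  if (n_jitter > 0L) {
    jits <- with_preserved_rng(opts$seed, {
      lapply(seq_len(n_jitter), function(i) {
        clip_to_bounds(jitter_start(h0)[spec$free], bounds$lower, bounds$upper)
      })
    })
    starts <- c(starts, jits)
  }

  best <- NULL
  best_rss <- Inf
  any_converged <- FALSE
  for (st in starts) {
    # per-start warnings (e.g. a start exhausting maxiter) are not errors:
    # failed starts are simply outvoted by converged ones
    ans <- tryCatch(
      suppressWarnings(
      minpack.lm::nls.lm(par = st, lower = bounds$lower, upper = bounds$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = opts$ftol, ptol = opts$ptol, maxiter = opts$maxiter,
                           maxfev = 100 * opts$maxiter))),
      error = function(e) NULL
    )
    if (is.null(ans)) next
    rss <- sum(ans$fvec^2)
    converged <- ans$info %in% 1:4
    if (converged) any_converged <- TRUE
    if (is.finite(rss) && rss < best_rss) {
      best_rss <- rss
      best <- ans
    }
  }
  if (is.null(best)) {
    stop_nk("optimizer failed from every start", class = "neurokin_numeric_error")
  }
  if (!any_converged) {
    stop_nk("optimizer did not converge after multistart; best candidate attached",
            class = "neurokin_numeric_error", best_candidate = best)
  }

  free_hat <- stats::setNames(as.numeric(best$par), names(best$par))
  params <- c(free_hat, fixed)[spec$params]
  fitted <- predict_pooled(pool, spec, params, cap_exponent = FALSE)
  RSS <- sum((y - fitted)^2)
  TSS <- sum((y - mean(y))^2)
  R2 <- if (TSS > 0) 1 - RSS / TSS else NA_real_

  flags <- character(0)
  if ("gamma" %in% spec$free) {
    g <- params[["gamma"]]
    if (g >= bounds$upper[["gamma"]] - 1e-3 || g <= bounds$lower[["gamma"]] + 1e-3) {
      flags <- c(flags, "gamma_at_boundary")
    }
  }
  if (spec$name == "secondary_risk" &&
      params[["A"]] < 1e-3 * max(abs(y))) {
    flags <- c(flags, "amplitude_near_zero_r0_unidentifiable")
  }
  if ("r0" %in% spec$free && params[["r0"]] <= bounds$lower[["r0"]] + 1e-12 &&
      spec$name != "constant_rate") {
    flags <- c(flags, "r0_at_zero_bound")
  }

  out <- structure(
    list(spec = spec, params = params, free = spec$free,
         RSS = RSS, TSS = TSS, n = n, p_free = p_free, R2 = R2,
         p_value = NA_real_, fitted = fitted, observed = y,
         days = pool$day, subject = pool$subject,
         flags = flags, convergence = best$info),
    class = "fit_result"
  )
  out$p_value <- tryCatch(regression_pvalue(out), error = function(e) NA_real_)
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s model (n = %d, %d free parameters)\n",
              x$spec$name, x$n, x$p_free))
  par_str <- paste(sprintf("%s = %.4g%s", names(x$params), x$params,
                           ifelse(names(x$params) %in% x$free, "", " (fixed)")),
                   collapse = ", ")
  cat(" ", par_str, "\n")
  cat(sprintf("  RSS = %.4g, R^2 = %.3f, P = %.3g\n", x$RSS, x$R2, x$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Coefficient of determination
#'
#' R^2 = 1 - RSS/TSS with TSS taken about the observed mean.
#'
#' @param observed,fitted Numeric vectors of equal length (n >= 2).
#' @return R^2 (can be negative for fits worse than the mean).
#' @export
r_squared <- function(observed, fitted) {
  observed <- as.numeric(observed); fitted <- as.numeric(fitted)
  if (length(observed) != length(fitted)) stop_nk("'observed' and 'fitted' must have equal length")
  if (length(observed) < 2L) stop_nk("need at least 2 observations")
  TSS <- sum((observed - mean(observed))^2)
  if (TSS == 0) stop_nk("observed values have zero variance; R^2 undefined")
  1 - sum((observed - fitted)^2) / TSS
}

#' Significance of a fit against the mean-only null
#'
#' Upper-tail F probability of F = ((TSS - RSS)/df1)/(RSS/df2) with
#' df1 = max(p_free - 1\[N0 free\], 1) and df2 = n - p_free: the level
#' parameter (N0 or N_B0), when free, plays the role of the null model's
#' mean, so only the remaining free parameters count as explanatory. This is
#' a declared convention of the package — nonlinear fit "P" values have no
#' single canonical definition.
#'
#' @param fit A `fit_result`.
#' @return One-sided p-value.
#' @export
regression_pvalue <- function(fit) {
  if (!inherits(fit, "fit_result")) stop_nk("'fit' must be a fit_result")
  level_free <- any(c("N0", "N_B0") %in% fit$free)
  df1 <- max(fit$p_free - as.integer(level_free), 1L)
  df2 <- fit$n - fit$p_free
  if (df2 < 1L) stop_nk("no residual degrees of freedom")
  if (fit$TSS <= 0) stop_nk("zero total sum of squares")
  Fstat <- ((fit$TSS - fit$RSS) / df1) / (fit$RSS / df2)
  if (!is.finite(Fstat)) return(0)  # RSS -> 0 limit
  f_tail_probability(max(Fstat, 0), df1, df2)
}

#' Upper-tail probability of the F distribution
#'
#' P(F_(df1, df2) >= F); the distribution backend for both the fit p-value
#' and the nested model-selection test.
#'
#' @param F Observed statistic (>= 0).
#' @param df1,df2 Degrees of freedom (>= 1).
#' @return Tail probability in (0, 1].
#' @export
f_tail_probability <- function(F, df1, df2) {
  assert_scalar_number(F, "F")
  if (F < 0) stop_nk("'F' must be >= 0")
  if (!is_scalar_number(df1) || df1 < 1 || !is_scalar_number(df2) || df2 < 1) {
    stop_nk("degrees of freedom must be >= 1")
  }
  stats::pf(F, df1, df2, lower.tail = FALSE)
}

#' Extra-sum-of-squares F-test between two nested fits
#'
#' F = ((RSS_reduced - RSS_full)/df1) / (RSS_full/df2) with
#' df1 = p_free(full) - p_free(reduced) and df2 = n - p_free(full), compared
#' to the upper tail of F_(df1, df2). Both fits must be on the same pooled
#' observations and the reduced model's free parameters must be a subset of
#' the full model's. If the optimizer left RSS_full above RSS_reduced, F is
#' floored at 0 with a warning — that situation signals an optimization
#' failure, not evidence for the reduced model.
#'
#' @param reduced,full `fit_result` objects.
#' @return An object of class `model_comparison` with `F`, `df1`, `df2`,
#'   `p_value` and both fits.
#' @export
nested_f_test <- function(reduced, full) {
  if (!inherits(reduced, "fit_result") || !inherits(full, "fit_result")) {
    stop_nk("'reduced' and 'full' must be fit_result objects")
  }
  if (!is_nested_spec(reduced$spec, full$spec)) {
    stop_nk(sprintf("model '%s' is not nested in model '%s'",
                    reduced$spec$name, full$spec$name))
  }
  if (reduced$n != full$n || !isTRUE(all.equal(sort(reduced$observed), sort(full$observed)))) {
    stop_nk("nested F-test requires both fits on the same observations")
  }
  df1 <- full$p_free - reduced$p_free
  df2 <- full$n - full$p_free
  if (df1 < 1L || df2 < 1L) stop_nk("invalid degrees of freedom for the nested test")
  num <- reduced$RSS - full$RSS
  if (num < 0) {
    warning("RSS of the full model exceeds the reduced model's; flooring F at 0 (optimizer failure signal)")
    num <- 0
  }
  Fstat <- if (full$RSS <= 0) {
    if (num <= 0) 0 else Inf
  } else {
    (num / df1) / (full$RSS / df2)
  }
  p <- if (is.infinite(Fstat)) 0 else f_tail_probability(Fstat, df1, df2)
  structure(
    list(reduced = reduced, full = full,
         F = Fstat, df1 = df1, df2 = df2, p_value = p),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %s vs %s: F(%d, %d) = %.3g, P = %.3g\n",
              x$reduced$spec$name, x$full$spec$name, x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' Ordinary least-squares fit of the linear secondary-degeneration law
#'
#' Regresses the secondary-region biomarker N_B on the primary-region
#' biomarker N_A: slope = k_t (coupling strength), intercept = N_B0 (the
#' plateau the secondary region approaches as the primary region degenerates
#' completely).
#'
#' @param N_A,N_B Numeric vectors of equal length (>= 3); `N_A` must vary.
#' @return An object of class `secondary_linear_fit` (also
#'   `secondary_coupling`) with `k_t`, `N_B0`, `A`, plus `r_squared`,
#'   `p_value` (two-sided slope test), `se_k_t` and `n`.
#' @export
fit_secondary_linear <- function(N_A, N_B) {
  N_A <- as.numeric(N_A); N_B <- as.numeric(N_B)
  if (length(N_A) != length(N_B)) stop_nk("'N_A' and 'N_B' must have equal length")
  if (length(N_A) < 3L) stop_nk("need at least 3 paired observations")
  if (stats::sd(N_A) == 0) {
    stop_nk("'N_A' is constant: degenerate design, slope not identifiable")
  }
  fit <- stats::lm(N_B ~ N_A)
  sm <- suppressWarnings(summary(fit))  # exact data trip lm's perfect-fit warning
  k_t <- unname(stats::coef(fit)[2L])
  N_B0 <- unname(stats::coef(fit)[1L])
  structure(
    list(k_t = k_t, N_B0 = N_B0, A = max(k_t, 0),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2L, 4L],
         se_k_t = sm$coefficients[2L, 2L],
         n = length(N_A)),
    class = c("secondary_linear_fit", "secondary_coupling")
  )
}

#' @export
print.secondary_linear_fit <- function(x, ...) {
  cat(sprintf("<secondary_linear_fit> N_B = %.4g + %.4g * N_A (n = %d, R^2 = %.3f, slope P = %.3g)\n",
              x$N_B0, x$k_t, x$n, x$r_squared, x$p_value))
  invisible(x)
}

#' Risk-based fit of secondary (transsynaptic) degeneration
#'
#' Fits N_B(t) = N_B0 + A exp(-R(t)) to a secondary-region series, where
#' R(t) is the cumulative risk of the *primary* insult (the subject's own
#' pressure series) and A = k_t N_A0 is a collapsed amplitude. Fix
#' `beta = 0` in the spec for the constant-risk variant; the two variants
#' are comparable via [nested_f_test]. When the fitted amplitude is
#' negligible the series is flat and r0 is unidentifiable; the result is
#' flagged `amplitude_near_zero_r0_unidentifiable` rather than rejected.
#'
#' @param degen_B A [degeneration_series] (or list) from the secondary
#'   region.
#' @param risk A [risk_series] (or list) of the primary risk biomarker.
#' @param spec A [model_spec] with name `"secondary_risk"`.
#' @param cfg An [excess_risk_config].
#' @param opts A [fit_options].
#' @return A `fit_result`.
#' @export
fit_secondary_risk <- function(degen_B, risk, spec = model_spec("secondary_risk"),
                               cfg = excess_risk_config(), opts = fit_options()) {
  if (!inherits(spec, "model_spec") || spec$name != "secondary_risk") {
    stop_nk("'spec' must be a model_spec with name 'secondary_risk'")
  }
  fit_kinetic_model(degen_B, risk, spec, cfg, opts)
}

#' Fit an ordered set of kinetic models and compare the nested pairs
#'
#' Fits each spec in order to the pooled glaucoma degeneration data of one
#' study and runs [nested_f_test] for every consecutive pair that is nested
#' (constant_risk -> variable_risk -> heterogeneity; the constant-rate model
#' is a different functional family and enters the table without an F-test).
#' Each full model is warm-started at the preceding reduced optimum, so RSS
#' never increases along a nested chain.
#'
#' @param dataset A [study_dataset].
#' @param specs List of [model_spec] objects, reduced to full.
#' @param cfg An [excess_risk_config].
#' @param opts A [fit_options].
#' @param region Which anatomical region's series to pool (default
#'   `"optic_nerve"`).
#' @param kind `"quantitative"` or `"relative"` series (default
#'   `"relative"`).
#' @return An object of class `model_comparison_set`: list with `fits`
#'   (named by model), `comparisons`, and `skipped` (non-nested consecutive
#'   pairs).
#' @export
compare_models <- function(dataset, specs, cfg = excess_risk_config(),
                           opts = fit_options(), region = "optic_nerve",
                           kind = c("relative", "quantitative")) {
  kind <- match.arg(kind)
  if (!inherits(dataset, "study_dataset")) stop_nk("'dataset' must be a study_dataset")
  if (!is.list(specs) || !all(vapply(specs, inherits, TRUE, "model_spec"))) {
    stop_nk("'specs' must be a list of model_spec objects")
  }
  glaucoma_ids <- unique(vapply(
    Filter(function(r) r$group == "glaucoma", dataset$risk_series),
    function(r) r$subject_id, character(1)))
  degen <- Filter(function(d) {
    d$region == region && d$kind == kind && d$eye == "affected" &&
      d$subject_id %in% glaucoma_ids
  }, dataset$degen_series)
  if (!length(degen)) {
    stop_nk(sprintf("no %s %s affected-eye series for glaucoma subjects in the dataset",
                    kind, region))
  }
  fits <- list()
  comparisons <- list()
  skipped <- character(0)
  prev <- NULL
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    extra <- list()
    if (!is.null(prev) && is_nested_spec(prev$spec, spec)) {
      extra <- list(prev$params)
    }
    fit <- fit_kinetic_model(degen, dataset$risk_series, spec, cfg, opts,
                             extra_starts = extra)
    fits[[spec$name]] <- fit
    if (!is.null(prev)) {
      if (is_nested_spec(prev$spec, spec)) {
        comparisons[[length(comparisons) + 1L]] <- nested_f_test(prev, fit)
      } else {
        skipped <- c(skipped, sprintf("%s -> %s", prev$spec$name, spec$name))
      }
    }
    prev <- fit
  }
  structure(list(fits = fits, comparisons = comparisons, skipped = skipped,
                 region = region, kind = kind),
            class = "model_comparison_set")
}

#' @export
print.model_comparison_set <- function(x, ...) {
  cat(sprintf("<model_comparison_set> %s %s data\n", x$kind, x$region))
  for (f in x$fits) {
    cat(sprintf("  %-14s R^2 = %.3f, RSS = %.4g\n", f$spec$name, f$R2, f$RSS))
  }
  for (cmp in x$comparisons) {
    cat(sprintf("  %s vs %s: F(%d,%d) = %.3g, P = %.3g\n",
                cmp$reduced$spec$name, cmp$full$spec$name,
                cmp$df1, cmp$df2, cmp$F, cmp$p_value))
  }
  invisible(x)
}
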