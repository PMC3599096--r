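# Shared fixture builders: everything is generated in code at test time.

make_risk <- function(subject_id = "s1", group = "glaucoma", eye = "affected",
                      days = c(0, 33, 61, 90, 120),
                      iop = c(23, 55, 48, 60, 52)) {
  risk_series(subject_id, group, eye, days = days, iop = iop)
}

make_degen <- function(subject_id = "s1", eye = "affected",
                       region = "optic_nerve",
                       days = c(33, 90), values = c(0.9, 0.7),
                       kind = "relative") {
  degeneration_series(subject_id, eye, region, days = days, values = values,
                      kind = kind)
}

# Generate the glaucoma-arm relative optic-nerve data only (the fitting
# input), much cheaper than a full simulate_study when looping.
gen_primary_arm <- function(seed, true_model = model_spec("variable_risk", relative = TRUE),
                            true_params = c(N0 = 1, r0 = 0.0019, beta = 0.057),
                            fa_noise_sd = 0.02, n_glaucoma = 5L) {
  cfg <- simulation_config(seed = seed, true_model = true_model,
                           true_params = true_params, fa_noise_sd = fa_noise_sd,
                           n_glaucoma = n_glaucoma)
  degen <- vector("list", n_glaucoma)
  risk <- vector("list", n_glaucoma)
  for (i in seq_len(n_glaucoma)) {
    eyes <- simulate_iop_course(cfg, i)
    risk[[i]] <- eyes$affected
    degen[[i]] <- simulate_degeneration(eyes$affected, cfg,
                                        seed = (seed + 7919L * i) %% 2147483647L)
  }
  list(degen = degen, risk = risk, cfg = cfg)
}

# Noiseless deterministic trajectory for one hand-built subject, used for
# exact-recovery tests.
gen_noiseless_subject <- function(subject_id = "s1",
                                  days = c(0, 20, 45, 70, 100, 130, 160),
                                  iop = c(23, 58, 49, 62, 51, 57, 54),
                                  q_days = c(45, 100, 160),
                                  N0 = 1, r0 = 0.002, beta = 0.06,
                                  threshold = 29) {
  rs <- risk_series(subject_id, "glaucoma", "affected", days, iop)
  R <- cumulative_risk(days, query_days = q_days, p = iop - threshold,
                       r0 = r0, beta = beta)
  ds <- degeneration_series(subject_id, "affected", "optic_nerve",
                            days = q_days, values = N0 * exp(-R$R),
                            kind = "relative")
  list(risk = rs, degen = ds)
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
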