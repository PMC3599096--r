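# Reporting layer: correlation validation of the histology assumption,
# table-shaped summaries, and the command entry points behind the CLI
# (simulate / fit / compare / validate-histology).

#' Spearman rank correlation with exact permutation p-values
#'
#' Computes the Spearman rank correlation and, for n <= `exact_max`, the
#' exact permutation p-values by enumerating all n! rank orders (feasible up
#' to n = 8, 40320 orders). For larger n the t-approximation
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom is used. With n = 5
#' perfectly concordant pairs the exact one-sided p is 1/120.
#'
#' @param x,y Numeric vectors, equal length >= 3, assumed untied.
#' @param exact_max Largest n for exact enumeration (default 8).
#' @return List with `estimate`, `p_one_sided`, `p_two_sided`, `method`
#'   (`"exact"` or `"approximate"`), `n`.
#' @export
spearman_exact <- function(x, y, exact_max = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop_nk("'x' and 'y' must have equal length")
  if (n < 3L) stop_nk("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    # correlation of fixed rx with every permutation of ry
    rho_all <- apply(perms, 1L, function(pp) stats::cor(rx, ry[pp]))
    eps <- 1e-12
    p_one <- mean(rho_all >= rho - eps)
    p_two <- mean(abs(rho_all) >= abs(rho) - eps)
    list(estimate = rho, p_one_sided = p_one, p_two_sided = p_two,
         method = "exact", n = n)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
    p_one <- stats::pt(tt, df = n - 2, lower.tail = FALSE)
    list(estimate = rho, p_one_sided = p_one, p_two_sided = 2 * min(p_one, 1 - p_one),
         method = "approximate", n = n)
  }
}

#' Validate the linearity assumption between FA and axon density
#'
#' The kinetic analysis assumes the imaging biomarker is linear in the
#' underlying axon density. This check computes (1) the Pearson correlation
#' between terminal FA and NF-positive axon density across nerves, with the
#' one-tailed t-based p-value t = r sqrt(df/(1-r^2)), df = n-2; and (2) the
#' Spearman rank correlation between the per-subject FA ratio and axon-count
#' ratio, with exact permutation p-values for n <= 8 (both one- and
#' two-sided are reported; sidedness is a reporting choice, not a model
#' property).
#'
#' @param degen_terminal `data.frame` with columns `subject_id`, `eye`, `fa`
#'   (terminal FA per nerve) and optionally `fa_ratio` on affected rows.
#' @param histology `data.frame` with columns `subject_id`, `eye`,
#'   `nf_density` and optionally `axon_count_ratio`.
#' @return An object of class `histology_validation`: list with `pearson`
#'   (estimate, t, df, p_one_sided) and `spearman` (see [spearman_exact]),
#'   the latter `NULL` when no ratio columns are available.
#' @export
validate_histology <- function(degen_terminal, histology) {
  if (!is.data.frame(degen_terminal) ||
      !all(c("subject_id", "eye", "fa") %in% names(degen_terminal))) {
    stop_nk("'degen_terminal' must have columns subject_id, eye, fa")
  }
  if (!is.data.frame(histology) ||
      !all(c("subject_id", "eye", "nf_density") %in% names(histology))) {
    stop_nk("'histology' must have columns subject_id, eye, nf_density")
  }
  merged <- merge(degen_terminal[c("subject_id", "eye", "fa")],
                  histology[c("subject_id", "eye", "nf_density")],
                  by = c("subject_id", "eye"))
  n <- nrow(merged)
  if (n < 3L) stop_nk("need at least 3 matched nerves")
  r <- stats::cor(merged$fa, merged$nf_density)
  df <- n - 2L
  tt <- r * sqrt(df / max(1 - r^2, 1e-15))
  pearson <- list(estimate = r, t = tt, df = df,
                  p_one_sided = stats::pt(tt, df = df, lower.tail = FALSE),
                  n = n)
  spearman <- NULL
  if ("axon_count_ratio" %in% names(histology)) {
    hr <- histology[histology$eye == "affected" & !is.na(histology$axon_count_ratio),
                    c("subject_id", "axon_count_ratio")]
    fr <- degen_terminal[degen_terminal$eye == "affected" &
                           !is.na(degen_terminal[["fa_ratio"]] %||% NA),
                         c("subject_id", "fa_ratio")]
    mr <- merge(fr, hr, by = "subject_id")
    if (nrow(mr) >= 3L) {
      spearman <- spearman_exact(mr$fa_ratio, mr$axon_count_ratio)
    }
  }
  structure(list(pearson = pearson, spearman = spearman),
            class = "histology_validation")
}

#' @export
print.histology_validation <- function(x, ...) {
  cat(sprintf("<histology_validation> Pearson r = %.3f (t = %.2f, df = %d, one-tailed P = %.3g)\n",
              x$pearson$estimate, x$pearson$t, x$pearson$df, x$pearson$p_one_sided))
  if (!is.null(x$spearman)) {
    cat(sprintf("  Spearman rho = %.3f (%s: one-sided P = %.4g, two-sided P = %.4g, n = %d)\n",
                x$spearman$estimate, x$spearman$method,
                x$spearman$p_one_sided, x$spearman$p_two_sided, x$spearman$n))
  }
  invisible(x)
}

#' Parameter table for a set of fitted models
#'
#' Renders a `model_comparison_set` as a table with one row per fitted model
#' (columns model, N0, r0, beta, gamma, R2, P, F, df1, df2, F_P), parameters
#' rounded to 2 significant figures in the printed form; the returned
#' data.frame keeps full precision.
#'
#' @param comparison_set A `model_comparison_set` from [compare_models].
#' @return A `data.frame` of class `report_table`.
#' @export
report_table <- function(comparison_set) {
  if (!inherits(comparison_set, "model_comparison_set")) {
    stop_nk("'comparison_set' must be a model_comparison_set")
  }
  tab <- do.call(rbind, lapply(comparison_set$fits, fit_to_row))
  for (cmp in comparison_set$comparisons) {
    i <- match(cmp$full$spec$name, tab$model)
    tab$F[i] <- cmp$F; tab$df1[i] <- cmp$df1; tab$df2[i] <- cmp$df2
    tab$F_P[i] <- cmp$p_value
  }
  rownames(tab) <- NULL
  class(tab) <- c("report_table", "data.frame")
  tab
}

#' @export
print.report_table <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) signif(v, 2))
  print(y, row.names = FALSE, na.print = "")
  invisible(x)
}

# ---- configuration files ----------------------------------------------------

# Flat `key = value` configuration parser (TOML-like scalars only): numbers,
# `true`/`false`, quoted strings, and 2-element ranges written `[a, b]`.
parse_config_file <- function(path) {
  if (!file.exists(path)) stop_nk(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1L]]
    if (length(m) != 3L) stop_nk(sprintf("malformed config line: '%s'", ln))
    key <- m[2L]; val <- trimws(m[3L])
    out[[key]] <- parse_config_value(val, key)
  }
  out
}

parse_config_value <- function(val, key) {
  if (grepl("^\\[.*\\]$", val)) {
    inner <- substr(val, 2L, nchar(val) - 1L)
    parts <- trimws(strsplit(inner, ",")[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) stop_nk(sprintf("config key '%s': non-numeric range '%s'", key, val))
    return(num)
  }
  if (val %in% c("true", "TRUE")) return(TRUE)
  if (val %in% c("false", "FALSE")) return(FALSE)
  if (grepl('^".*"$', val)) return(substr(val, 2L, nchar(val) - 1L))
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) stop_nk(sprintf("config key '%s': cannot parse value '%s'", key, val))
  num
}

# Build a simulation_config from a flat key/value list; unknown keys are an
# error naming the key. `true_model` is given by name (+ `relative`).
config_from_list <- function(values, seed) {
  allowed <- c("n_glaucoma", "n_control", "follow_up_days", "iop_interval_days",
               "baseline_iop_mean", "baseline_iop_sd",
               "affected_iop_mean", "affected_iop_sd", "affected_iop_within_sd",
               "true_model", "relative", "true_r0", "true_beta", "true_N0",
               "true_gamma", "fa_noise_sd", "n_mri_sessions", "n_replicates",
               "quant_fa_baseline", "quant_fa_baseline_sd",
               "secondary_k_t", "secondary_N_B0", "threshold",
               "histology_slope", "histology_intercept", "histology_noise_sd")
  unknown <- setdiff(names(values), allowed)
  if (length(unknown)) {
    stop_nk(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  v <- function(key, default) values[[key]] %||% default
  relative <- isTRUE(v("relative", TRUE))
  model_name <- v("true_model", "variable_risk")
  tp <- c(N0 = as.numeric(v("true_N0", 1)), r0 = as.numeric(v("true_r0", 0.0019)),
          beta = as.numeric(v("true_beta", 0.057)))
  if (model_name == "heterogeneity") tp <- c(tp, gamma = as.numeric(v("true_gamma", 1)))
  cfg <- simulation_config(
    n_glaucoma = v("n_glaucoma", 5L), n_control = v("n_control", 3L),
    follow_up_days = v("follow_up_days", c(33, 168)),
    iop_interval_days = v("iop_interval_days", c(3, 28)),
    baseline_iop = c(mean = as.numeric(v("baseline_iop_mean", 23.2)),
                     sd = as.numeric(v("baseline_iop_sd", 0.8))),
    affected_iop = c(mean = as.numeric(v("affected_iop_mean", 54.9)),
                     sd = as.numeric(v("affected_iop_sd", 9.4))),
    affected_iop_within_sd = v("affected_iop_within_sd", 8),
    true_model = model_spec(model_name, relative = relative),
    true_params = tp,
    fa_noise_sd = v("fa_noise_sd", 0.02),
    n_mri_sessions = v("n_mri_sessions", c(2L, 3L)),
    n_replicates = v("n_replicates", 3L),
    quant_fa_baseline = v("quant_fa_baseline", 0.73),
    quant_fa_baseline_sd = v("quant_fa_baseline_sd", 0.015),
    secondary_k_t = v("secondary_k_t", 0.5),
    secondary_N_B0 = v("secondary_N_B0", 0.4),
    threshold = v("threshold", 29),
    seed = seed
  )
  hcfg <- histology_config(
    slope = v("histology_slope", 1),
    intercept = v("histology_intercept", 0.05),
    noise_sd = v("histology_noise_sd", 0.085)
  )
  list(cfg = cfg, hcfg = hcfg)
}

# ---- command entry points ---------------------------------------------------

#' Simulate a study and write its interchange files
#'
#' Writes `risk.csv`, `degeneration_quantitative.csv`,
#' `degeneration_relative.csv`, `histology.csv` and a `provenance.json`
#' (config values, seed, package version, output file hashes) sufficient to
#' re-run the simulation bit-identically.
#'
#' @param config Optional path to a flat `key = value` config file; `NULL`
#'   uses the defaults.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named character vector of written paths.
#' @export
cmd_simulate <- function(config = NULL, seed, out_dir) {
  values <- if (is.null(config)) list() else parse_config_file(config)
  built <- config_from_list(values, seed = seed)
  study <- simulate_study(built$cfg, built$hcfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    risk = file.path(out_dir, "risk.csv"),
    degeneration_quantitative = file.path(out_dir, "degeneration_quantitative.csv"),
    degeneration_relative = file.path(out_dir, "degeneration_relative.csv"),
    histology = file.path(out_dir, "histology.csv"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_risk_csv(study$risk_series, paths[["risk"]])
  quant <- Filter(function(d) d$kind == "quantitative", study$degen_series)
  rel <- Filter(function(d) d$kind == "relative", study$degen_series)
  write_degeneration_csv(quant, paths[["degeneration_quantitative"]])
  write_degeneration_csv(rel, paths[["degeneration_relative"]])
  write_histology_csv(study$histology, paths[["histology"]])
  hashes <- vapply(paths[1:4], function(p) {
    as.character(tools::md5sum(p))
  }, character(1))
  provenance <- list(
    tool = "neurokin", version = as.character(utils::packageVersion("neurokin")),
    command = "simulate", seed = as.integer(seed),
    config_file = config %||% NA,
    config = values, file_md5 = as.list(hashes)
  )
  jsonlite::write_json(provenance, paths[["provenance"]],
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Fit one kinetic model to study files and write a report
#'
#' @param risk_path Risk CSV path.
#' @param degen_path Degeneration CSV path.
#' @param model Model name (`"constant_rate"`, `"constant_risk"`,
#'   `"variable_risk"`, `"heterogeneity"`).
#' @param relative Fix N0 = 1 (ratio data). Default: the file's kind.
#' @param threshold Excess-pressure threshold, mmHg (default 29).
#' @param out Output CSV path (JSON sidecar written alongside).
#' @param region Anatomical region to fit (default `"optic_nerve"`).
#' @param opts A [fit_options].
#' @return The `fit_result`, invisibly.
#' @export
cmd_fit <- function(risk_path, degen_path, model = "variable_risk",
                    relative = NULL, threshold = 29, out,
                    region = "optic_nerve", opts = fit_options()) {
  risk <- read_risk_csv(risk_path)
  degen <- read_degeneration_csv(degen_path)
  kind <- unique(vapply(degen, function(d) d$kind, character(1)))[1L]
  relative <- relative %||% (kind == "relative")
  glaucoma_ids <- unique(vapply(
    Filter(function(r) r$group == "glaucoma", risk), function(r) r$subject_id, character(1)))
  degen <- Filter(function(d) {
    d$region == region && d$eye == "affected" && d$subject_id %in% glaucoma_ids
  }, degen)
  if (!length(degen)) stop_nk("no matching affected-eye series for glaucoma subjects")
  spec <- model_spec(model, relative = relative)
  fit <- fit_kinetic_model(degen, risk, spec,
                           cfg = excess_risk_config(threshold = threshold),
                           opts = opts)
  write_fit_report(list(fit), out)
  invisible(fit)
}

#' Fit and compare an ordered list of kinetic models, writing a report
#'
#' Consecutive pairs must be nested (the constant-rate model may appear and
#' simply enters the table without an F-test); a genuinely non-nested pair
#' is an error naming the pair.
#'
#' @param risk_path,degen_path Input CSV paths.
#' @param models Character vector of model names, reduced to full (>= 2).
#' @param out Output CSV path (JSON sidecar written alongside).
#' @param relative,threshold,region,opts As in [cmd_fit].
#' @return The `model_comparison_set`, invisibly.
#' @export
cmd_compare <- function(risk_path, degen_path, models, out,
                        relative = NULL, threshold = 29,
                        region = "optic_nerve", opts = fit_options()) {
  if (length(models) < 2L) stop_nk("need at least 2 models to compare")
  risk <- read_risk_csv(risk_path)
  degen <- read_degeneration_csv(degen_path)
  kind <- unique(vapply(degen, function(d) d$kind, character(1)))[1L]
  relative <- relative %||% (kind == "relative")
  specs <- lapply(models, model_spec, relative = relative)
  for (i in seq_len(length(specs) - 1L)) {
    a <- specs[[i]]; b <- specs[[i + 1L]]
    if (!is_nested_spec(a, b) && a$name != "constant_rate" && b$name != "constant_rate") {
      stop_nk(sprintf("models '%s' and '%s' are not nested", a$name, b$name))
    }
  }
  dataset <- study_dataset(unname(risk), unname(degen))
  cmp <- compare_models(dataset, specs,
                        cfg = excess_risk_config(threshold = threshold),
                        opts = opts, region = region, kind = kind)
  write_fit_report(cmp, out)
  invisible(cmp)
}
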