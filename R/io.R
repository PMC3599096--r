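# Readers/writers for the longitudinal CSV interchange formats.
#
# Fixed dialect: UTF-8, comma separator, "." decimal, mandatory header.
# Risk CSV:          subject_id,group,eye,day,iop_mmHg
# Degeneration CSV:  subject_id,eye,region,day,value,n_replicates
#   (kind is carried by an optional leading "# kind: relative" comment line,
#    or forced by the `kind` argument)
# Histology CSV:     subject_id,eye,nf_density,axon_count_ratio

read_checked_csv <- function(path, required, label) {
  if (!file.exists(path)) stop_nk(sprintf("%s file not found: %s", label, path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                    fileEncoding = "UTF-8"),
    error = function(e) stop_nk(sprintf("cannot parse %s file '%s': %s",
                                        label, path, conditionMessage(e)))
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_nk(sprintf("%s file '%s' is missing column(s): %s",
                    label, path, paste(missing, collapse = ", ")))
  }
  df
}

check_numeric_column <- function(df, col, path, positive = FALSE) {
  raw <- df[[col]]
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(val) | !is.finite(val) | (positive & val <= 0))
  if (length(bad)) {
    stop_nk(sprintf("file '%s': non-numeric or invalid '%s' at data row %d (value '%s')",
                    path, col, bad[1L], as.character(raw[bad[1L]])))
  }
  val
}

#' Read longitudinal risk-biomarker measurements from CSV
#'
#' Expects columns `subject_id,group,eye,day,iop_mmHg`. Rows are grouped by
#' (subject, eye) into one [risk_series] each, sorted by day. Duplicate
#' (subject, eye, day) rows and non-numeric values are parse errors naming
#' the offending row.
#'
#' @param path Path to the CSV file.
#' @return Named list of [risk_series] (names `subjectid.eye`).
#' @export
read_risk_csv <- function(path) {
  df <- read_checked_csv(path, c("subject_id", "group", "eye", "day", "iop_mmHg"), "risk")
  if (!nrow(df)) stop_nk(sprintf("risk file '%s' has no data rows", path))
  df$day <- check_numeric_column(df, "day", path)
  df$iop_mmHg <- check_numeric_column(df, "iop_mmHg", path, positive = TRUE)
  bad_group <- which(!df$group %in% c("glaucoma", "control"))
  if (length(bad_group)) {
    stop_nk(sprintf("file '%s': unknown group '%s' at data row %d",
                    path, df$group[bad_group[1L]], bad_group[1L]))
  }
  bad_eye <- which(!df$eye %in% c("affected", "fellow"))
  if (length(bad_eye)) {
    stop_nk(sprintf("file '%s': unknown eye '%s' at data row %d",
                    path, df$eye[bad_eye[1L]], bad_eye[1L]))
  }
  key <- paste(df$subject_id, df$eye, df$day, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop_nk(sprintf("file '%s': duplicate (subject, eye, day) at data row %d (%s, %s, day %g)",
                    path, i, df$subject_id[i], df$eye[i], df$day[i]))
  }
  out <- list()
  for (grp in split(df, paste(df$subject_id, df$eye, sep = "."))) {
    grp <- grp[order(grp$day), , drop = FALSE]
    s <- risk_series(grp$subject_id[1L], grp$group[1L], grp$eye[1L],
                     days = grp$day, iop = grp$iop_mmHg)
    out[[paste(s$subject_id, s$eye, sep = ".")]] <- s
  }
  out[order(names(out))]
}

#' Write risk series to the interchange CSV format
#'
#' @param risk_list List of [risk_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_csv <- function(risk_list, path) {
  risk_list <- as_series_list(risk_list, "risk_series")
  rows <- do.call(rbind, lapply(risk_list, function(r) {
    data.frame(subject_id = r$subject_id, group = r$group, eye = r$eye,
               day = r$days, iop_mmHg = r$iop, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read longitudinal degeneration-biomarker measurements from CSV
#'
#' Expects columns `subject_id,eye,region,day,value,n_replicates`. The value
#' kind (`quantitative` in (0, 1], or `relative` affected/fellow ratio) is
#' taken from a leading `# kind: relative` comment line if present, and can
#' be forced with the `kind` argument. Values are validated per kind; a
#' quantitative value outside (0, 1] is a validation error.
#'
#' @param path Path to the CSV file.
#' @param kind Optional `"quantitative"` or `"relative"`, overriding the
#'   file's metadata line (default: metadata line, else quantitative).
#' @return Named list of [degeneration_series].
#' @export
read_degeneration_csv <- function(path, kind = NULL) {
  if (!file.exists(path)) stop_nk(sprintf("degeneration file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  file_kind <- NULL
  m <- regmatches(first, regexec("^#\\s*kind:\\s*(quantitative|relative)\\s*$", first))[[1L]]
  if (length(m) == 2L) file_kind <- m[2L]
  kind <- kind %||% file_kind %||% "quantitative"
  kind <- match.arg(kind, c("quantitative", "relative"))
  df <- read_checked_csv(path, c("subject_id", "eye", "region", "day", "value", "n_replicates"),
                         "degeneration")
  if (!nrow(df)) stop_nk(sprintf("degeneration file '%s' has no data rows", path))
  df$day <- check_numeric_column(df, "day", path)
  df$value <- check_numeric_column(df, "value", path, positive = TRUE)
  df$n_replicates <- check_numeric_column(df, "n_replicates", path, positive = TRUE)
  if (kind == "quantitative") {
    bad <- which(df$value > 1)
    if (length(bad)) {
      stop_nk(sprintf("file '%s': quantitative value %g > 1 at data row %d",
                      path, df$value[bad[1L]], bad[1L]))
    }
  }
  key <- paste(df$subject_id, df$eye, df$region, df$day, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop_nk(sprintf("file '%s': duplicate (subject, eye, region, day) at data row %d",
                    path, i))
  }
  out <- list()
  for (grp in split(df, paste(df$subject_id, df$eye, df$region, sep = "."))) {
    grp <- grp[order(grp$day), , drop = FALSE]
    s <- degeneration_series(grp$subject_id[1L], grp$eye[1L], grp$region[1L],
                             days = grp$day, values = grp$value, kind = kind,
                             n_replicates = as.integer(grp$n_replicates))
    out[[paste(s$subject_id, s$eye, s$region, sep = ".")]] <- s
  }
  out[order(names(out))]
}

#' Write degeneration series to the interchange CSV format
#'
#' All series in one file must share a kind; it is recorded as a leading
#' `# kind:` comment line so the file round-trips without external flags.
#'
#' @param degen_list List of [degeneration_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_degeneration_csv <- function(degen_list, path) {
  degen_list <- as_series_list(degen_list, "degeneration_series")
  kinds <- unique(vapply(degen_list, function(d) d$kind, character(1)))
  if (length(kinds) != 1L) {
    stop_nk("all series written to one degeneration CSV must share a kind")
  }
  rows <- do.call(rbind, lapply(degen_list, function(d) {
    data.frame(subject_id = d$subject_id, eye = d$eye, region = d$region,
               day = d$days, value = d$values, n_replicates = d$n_replicates,
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", kinds), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a terminal histology table to CSV
#'
#' @param histology `data.frame` with columns `subject_id`, `eye`,
#'   `nf_density`, `axon_count_ratio`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histology_csv <- function(histology, path) {
  utils::write.csv(histology, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a terminal histology table from CSV
#'
#' @param path Path to a CSV with columns `subject_id`, `eye`, `nf_density`
#'   (and optionally `axon_count_ratio`, `fa`).
#' @return A `data.frame`.
#' @export
read_histology_csv <- function(path) {
  df <- read_checked_csv(path, c("subject_id", "eye", "nf_density"), "histology")
  df$nf_density <- check_numeric_column(df, "nf_density", path)
  df
}

#' Derive a relative (affected/fellow) degeneration series
#'
#' Elementwise ratio of the affected-eye to the fellow-eye series measured on
#' the same days — the relative-biomarker convention that cancels
#' session-level measurement error shared by both eyes.
#'
#' @param affected,fellow [degeneration_series] for the same subject and
#'   region, on identical day grids.
#' @return A [degeneration_series] with `kind = "relative"`.
#' @export
derive_relative_series <- function(affected, fellow) {
  if (!inherits(affected, "degeneration_series") || !inherits(fellow, "degeneration_series")) {
    stop_nk("both arguments must be degeneration_series")
  }
  if (affected$subject_id != fellow$subject_id) {
    stop_nk("affected and fellow series must come from the same subject")
  }
  if (affected$region != fellow$region) {
    stop_nk("affected and fellow series must come from the same region")
  }
  if (length(affected$days) != length(fellow$days) ||
      !isTRUE(all.equal(affected$days, fellow$days))) {
    stop_nk("affected and fellow series must share identical measurement days")
  }
  if (any(fellow$values <= 0)) stop_nk("fellow values must be > 0 to form a ratio")
  degeneration_series(
    subject_id = affected$subject_id, eye = "affected", region = affected$region,
    days = affected$days, values = affected$values / fellow$values,
    kind = "relative",
    n_replicates = pmin(affected$n_replicates, fellow$n_replicates)
  )
}

# ---- fit report -------------------------------------------------------------

fit_to_row <- function(fit) {
  p <- fit$params
  g <- function(nm) if (nm %in% names(p)) p[[nm]] else NA_real_
  data.frame(
    model = fit$spec$name,
    N0 = if ("N0" %in% names(p)) p[["N0"]] else g("N_B0"),
    r0 = g("r0"), beta = g("beta"), gamma = g("gamma"),
    R2 = fit$R2, P = fit$p_value,
    F = NA_real_, df1 = NA_integer_, df2 = NA_integer_, F_P = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Write a model-fit report (CSV table + full-precision JSON sidecar)
#'
#' Produces a parameter table shaped like the package's standard report: one
#' row per fitted model with columns
#' `model,N0,r0,beta,gamma,R2,P,F,df1,df2,F_P`; F-test columns are filled on
#' the row of the *full* model of each comparison and left blank elsewhere.
#' A JSON sidecar (`<path>.json`) stores every parameter at full precision,
#' so the report round-trips bit-exactly through [read_fit_report].
#'
#' @param results A `model_comparison_set`, or a list of `fit_result` and
#'   `model_comparison` objects sharing one dataset.
#' @param path Output CSV path (the JSON sidecar is `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(results, path) {
  if (inherits(results, "model_comparison_set")) {
    results <- c(unname(results$fits), results$comparisons)
  }
  fits <- Filter(function(x) inherits(x, "fit_result"), results)
  comps <- Filter(function(x) inherits(x, "model_comparison"), results)
  if (!length(fits)) stop_nk("no fit results to report")
  tab <- do.call(rbind, lapply(fits, fit_to_row))
  for (cmp in comps) {
    i <- match(cmp$full$spec$name, tab$model)
    if (!is.na(i)) {
      tab$F[i] <- cmp$F
      tab$df1[i] <- cmp$df1
      tab$df2[i] <- cmp$df2
      tab$F_P[i] <- cmp$p_value
    }
  }
  ok <- tryCatch({
    utils::write.csv(tab, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_nk(sprintf("cannot write report to '%s'", path))
  payload <- list(
    fits = lapply(fits, function(f) {
      list(model = f$spec$name,
           params = as.list(f$params),
           free = f$free,
           RSS = f$RSS, TSS = f$TSS, n = f$n, p_free = f$p_free,
           R2 = f$R2, p_value = f$p_value,
           flags = f$flags)
    }),
    comparisons = lapply(comps, function(cmp) {
      list(reduced = cmp$reduced$spec$name, full = cmp$full$spec$name,
           F = cmp$F, df1 = cmp$df1, df2 = cmp$df2, p_value = cmp$p_value)
    })
  )
  # 17 significant digits so every double round-trips bit-exactly
  jsonlite::write_json(payload, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read back the JSON sidecar of a fit report
#'
#' @param path Path to the JSON sidecar written by [write_fit_report].
#' @return A list with `fits` and `comparisons`, parameters at full
#'   precision.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop_nk(sprintf("report file not found: %s", path))
  jsonlite::read_json(path, simplifyVector = FALSE)
}
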