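#' Longitudinal risk-biomarker series for one subject-eye
#'
#' A `risk_series` holds an irregular time series of the pathogenic risk
#' biomarker — intraocular pressure (IOP, mmHg) in the glaucoma application —
#' for a single subject and eye. Days are offsets from the induction event
#' (day 0 = first laser treatment in the experimental glaucoma model).
#'
#' @param subject_id Character scalar identifying the subject.
#' @param group `"glaucoma"` or `"control"`.
#' @param eye `"affected"` or `"fellow"`.
#' @param days Numeric vector of measurement days (>= 0), strictly increasing.
#' @param iop Numeric vector of pressures (mmHg, finite and > 0), same length
#'   as `days`.
#'
#' @return An object of class `risk_series`.
#' @examples
#' rs <- risk_series("s1", "glaucoma", "affected",
#'                   days = c(0, 33, 61), iop = c(23, 55, 49))
#' rs
#' @export
risk_series <- function(subject_id, group = c("glaucoma", "control"),
                        eye = c("affected", "fellow"), days, iop) {
  group <- match.arg(group)
  eye <- match.arg(eye)
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id)) {
    stop_nk("'subject_id' must be a single string")
  }
  days <- as.numeric(days)
  iop <- as.numeric(iop)
  if (length(days) != length(iop)) {
    stop_nk("'days' and 'iop' must have the same length")
  }
  if (length(days) && (anyNA(days) || any(!is.finite(days)) || any(days < 0))) {
    stop_nk("'days' must be finite and >= 0")
  }
  if (length(days) > 1L && any(diff(days) <= 0)) {
    stop_nk("'days' must be strictly increasing")
  }
  if (length(iop) && (anyNA(iop) || any(!is.finite(iop)) || any(iop <= 0))) {
    stop_nk("'iop' must be finite and positive (mmHg)")
  }
  structure(
    list(subject_id = subject_id, group = group, eye = eye,
         days = days, iop = iop),
    class = "risk_series"
  )
}

#' @export
print.risk_series <- function(x, ...) {
  cat(sprintf("<risk_series> subject %s, %s %s eye: %d IOP measurements over days [%g, %g]\n",
              x$subject_id, x$group, x$eye, length(x$days),
              if (length(x$days)) min(x$days) else NA, if (length(x$days)) max(x$days) else NA))
  invisible(x)
}

#' Longitudinal degeneration-biomarker series for one subject-eye-region
#'
#' A `degeneration_series` holds the integrity biomarker N(t) — fractional
#' anisotropy (FA) in the glaucoma application — for one subject, eye and
#' anatomical region. `kind = "quantitative"` values are FA in (0, 1];
#' `kind = "relative"` values are ratios of the affected to the fellow side
#' and may exceed 1. Values are assumed to already be averaged across
#' `n_replicates` repeated scans per session; the replicate count is carried
#' as metadata only.
#'
#' @param subject_id Character scalar.
#' @param eye `"affected"` or `"fellow"`.
#' @param region `"optic_nerve"`, `"optic_radiation"` or `"other"`.
#' @param days Numeric vector of measurement days (>= 0), strictly increasing.
#' @param values Numeric vector of biomarker values (> 0; additionally <= 1
#'   when `kind = "quantitative"`).
#' @param kind `"quantitative"` or `"relative"`.
#' @param n_replicates Integer replicate count per time point (default 3).
#'
#' @return An object of class `degeneration_series`.
#' @export
degeneration_series <- function(subject_id, eye = c("affected", "fellow"),
                                region = c("optic_nerve", "optic_radiation", "other"),
                                days, values,
                                kind = c("quantitative", "relative"),
                                n_replicates = 3L) {
  eye <- match.arg(eye)
  region <- match.arg(region)
  kind <- match.arg(kind)
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id)) {
    stop_nk("'subject_id' must be a single string")
  }
  days <- as.numeric(days)
  values <- as.numeric(values)
  if (length(days) != length(values)) {
    stop_nk("'days' and 'values' must have the same length")
  }
  if (length(days) && (anyNA(days) || any(!is.finite(days)) || any(days < 0))) {
    stop_nk("'days' must be finite and >= 0")
  }
  if (length(days) > 1L && any(diff(days) <= 0)) {
    stop_nk("'days' must be strictly increasing")
  }
  if (length(values) && (anyNA(values) || any(!is.finite(values)) || any(values <= 0))) {
    stop_nk("'values' must be finite and > 0")
  }
  if (kind == "quantitative" && length(values) && any(values > 1)) {
    stop_nk("quantitative biomarker values must lie in (0, 1]")
  }
  n_replicates <- as.integer(n_replicates)
  if (length(n_replicates) == 1L) n_replicates <- rep(n_replicates, length(days))
  if (length(n_replicates) != length(days) || any(n_replicates < 1L)) {
    stop_nk("'n_replicates' must be a positive integer (scalar or per time point)")
  }
  structure(
    list(subject_id = subject_id, eye = eye, region = region,
         days = days, values = values, kind = kind,
         n_replicates = n_replicates),
    class = "degeneration_series"
  )
}

#' @export
print.degeneration_series <- function(x, ...) {
  cat(sprintf("<degeneration_series> subject %s, %s eye, %s (%s): %d points over days [%g, %g]\n",
              x$subject_id, x$eye, x$region, x$kind, length(x$days),
              if (length(x$days)) min(x$days) else NA, if (length(x$days)) max(x$days) else NA))
  invisible(x)
}

#' Bundle of a study's longitudinal series and terminal histology
#'
#' Collects all risk series, all degeneration series, and the optional
#' terminal histology table of a study. Construction checks that every
#' degeneration series of a glaucoma subject has a matching affected-eye risk
#' series spanning its measurement days, so downstream cumulative-risk
#' integration never needs to extrapolate.
#'
#' @param risk_series List of [risk_series] objects.
#' @param degen_series List of [degeneration_series] objects.
#' @param histology Optional `data.frame` with columns `subject_id`, `eye`,
#'   `nf_density` (axon density per unit area) and `axon_count_ratio`.
#'
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(risk_series, degen_series, histology = NULL) {
  if (!is.list(risk_series) || !all(vapply(risk_series, inherits, TRUE, "risk_series"))) {
    stop_nk("'risk_series' must be a list of risk_series objects")
  }
  if (!is.list(degen_series) || !all(vapply(degen_series, inherits, TRUE, "degeneration_series"))) {
    stop_nk("'degen_series' must be a list of degeneration_series objects")
  }
  if (!is.null(histology)) {
    if (!is.data.frame(histology) ||
        !all(c("subject_id", "eye", "nf_density") %in% names(histology))) {
      stop_nk("'histology' must be a data.frame with subject_id, eye, nf_density columns")
    }
  }
  glaucoma_ids <- unique(vapply(
    Filter(function(r) r$group == "glaucoma", risk_series),
    function(r) r$subject_id, character(1)
  ))
  for (d in degen_series) {
    if (!d$subject_id %in% glaucoma_ids) next
    rs <- find_risk_series(risk_series, d$subject_id, "affected")
    if (is.null(rs)) {
      stop_nk(sprintf("no affected-eye risk series for glaucoma subject '%s'", d$subject_id))
    }
    if (length(d$days) &&
        (min(d$days) < min(rs$days) || max(d$days) > max(rs$days))) {
      stop_nk(sprintf(
        "degeneration series for subject '%s' (%s, %s) extends outside its risk series span [%g, %g]",
        d$subject_id, d$eye, d$region, min(rs$days), max(rs$days)))
    }
  }
  structure(
    list(risk_series = risk_series, degen_series = degen_series,
         histology = histology),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  groups <- vapply(x$risk_series, function(r) r$group, character(1))
  ids <- vapply(x$risk_series, function(r) r$subject_id, character(1))
  cat(sprintf("<study_dataset> %d subjects (%d glaucoma, %d control), %d risk series, %d degeneration series%s\n",
              length(unique(ids)),
              length(unique(ids[groups == "glaucoma"])),
              length(unique(ids[groups == "control"])),
              length(x$risk_series), length(x$degen_series),
              if (is.null(x$histology)) "" else sprintf(", histology for %d nerves", nrow(x$histology))))
  invisible(x)
}

# Locate a subject-eye risk series in a list; NULL when absent.
find_risk_series <- function(risk_list, subject_id, eye) {
  for (r in risk_list) {
    if (r$subject_id == subject_id && r$eye == eye) return(r)
  }
  NULL
}

find_degen_series <- function(degen_list, subject_id, eye, region) {
  for (d in degen_list) {
    if (d$subject_id == subject_id && d$eye == eye && d$region == region) return(d)
  }
  NULL
}

#' Time-indexed cumulative risk curve
#'
#' The cumulative risk R(t) = integral of the instantaneous degeneration
#' hazard r(t) from the start of a series up to each day — the decay abscissa
#' of the risk-based survival models. R starts at 0, is nondecreasing and
#' finite.
#'
#' @param days Numeric vector of days, strictly increasing.
#' @param R Numeric vector of cumulative risk values (dimensionless).
#' @return An object of class `cumulative_risk_curve`.
#' @export
cumulative_risk_curve <- function(days, R) {
  days <- as.numeric(days)
  R <- as.numeric(R)
  if (length(days) != length(R)) stop_nk("'days' and 'R' must have the same length")
  if (length(days) > 1L && any(diff(days) <= 0)) stop_nk("'days' must be strictly increasing")
  if (anyNA(R) || any(!is.finite(R))) stop_nk("cumulative risk must be finite")
  if (length(R) > 1L && any(diff(R) < -1e-12)) stop_nk("cumulative risk must be nondecreasing")
  if (length(R) && any(R < -1e-12)) stop_nk("cumulative risk must be >= 0")
  structure(list(days = days, R = pmax(R, 0)), class = "cumulative_risk_curve")
}

#' @export
print.cumulative_risk_curve <- function(x, ...) {
  cat(sprintf("<cumulative_risk_curve> %d points, R in [%g, %g]\n",
              length(x$days), min(x$R), max(x$R)))
  invisible(x)
}
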