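# Domain types for longitudinal patient courses and the CSV/JSON interchange
# formats every other module consumes.

LESION_COLS <- c("lesion_id", "timepoint_date", "longest_diameter_mm",
                 "iodine_mg_per_ml", "aortic_iodine_mg_per_ml", "location")
CA125_COLS  <- c("sample_date", "value_u_per_ml")
LINE_COLS   <- c("line_index", "start_date", "end_date")

empty_lesions <- function() {
  data.frame(lesion_id = character(), timepoint_date = as.Date(character()),
             longest_diameter_mm = numeric(), iodine_mg_per_ml = numeric(),
             aortic_iodine_mg_per_ml = numeric(), location = character(),
             stringsAsFactors = FALSE)
}
empty_ca125 <- function() {
  data.frame(sample_date = as.Date(character()), value_u_per_ml = numeric(),
             stringsAsFactors = FALSE)
}
empty_lines <- function() {
  data.frame(line_index = integer(), start_date = as.Date(character()),
             end_date = as.Date(character()), stringsAsFactors = FALSE)
}

#' Construct a patient course
#'
#' A patient course is the full longitudinal record for one patient: target
#' lesion measurements (longest diameter in mm and, where dual-energy CT was
#' acquired, lesion and aortic iodine concentration in mg/mL) grouped by
#' lesion and imaging timepoint, a dated CA125 series against the assay's
#' upper limit of normal (ULN), treatment lines, and outcome dates.
#'
#' A diameter of 0 encodes complete disappearance of a lesion; a lesion that
#' was simply not measured at a timepoint has no row at that timepoint.
#'
#' @param patient_id Opaque patient identifier.
#' @param lesions data.frame with columns `lesion_id`, `timepoint_date`,
#'   `longest_diameter_mm`, `iodine_mg_per_ml`, `aortic_iodine_mg_per_ml`,
#'   `location` (iodine columns may be `NA` for single-energy scans).
#' @param ca125 data.frame with columns `sample_date`, `value_u_per_ml`.
#' @param treatment_lines data.frame with columns `line_index`, `start_date`,
#'   `end_date` (`end_date` may be `NA` for an ongoing line).
#' @param uln_u_per_ml CA125 upper limit of normal (U/mL). Defaults to 35,
#'   a common assay ULN; configure to the laboratory's value.
#' @param setting `"first_line"` or `"relapse"`.
#' @param death_date,last_followup_date Outcome dates (`death_date` optional).
#' @param therapy_change_dates Vector of dates on which therapy was changed.
#' @return An object of class `patient_course`.
#' @export
patient_course <- function(patient_id,
                           lesions = empty_lesions(),
                           ca125 = empty_ca125(),
                           treatment_lines = empty_lines(),
                           uln_u_per_ml = 35,
                           setting = c("relapse", "first_line"),
                           death_date = NULL,
                           therapy_change_dates = as.Date(character()),
                           last_followup_date = NULL) {
  setting <- match.arg(setting)
  lesions$timepoint_date <- parse_iso_date(lesions$timepoint_date)
  lesions$lesion_id <- as.character(lesions$lesion_id)
  if (is.null(lesions$location)) lesions$location <- NA_character_
  ca125$sample_date <- parse_iso_date(ca125$sample_date)
  treatment_lines$start_date <- parse_iso_date(treatment_lines$start_date)
  treatment_lines$end_date <- parse_iso_date(treatment_lines$end_date %||%
                                               rep(NA, nrow(treatment_lines)))
  death_date <- if (is.null(death_date) || all(is.na(death_date)))
    as.Date(NA) else parse_iso_date(death_date)
  therapy_change_dates <- parse_iso_date(therapy_change_dates)
  therapy_change_dates <- sort(therapy_change_dates[!is.na(therapy_change_dates)])
  if (is.null(last_followup_date) || all(is.na(last_followup_date))) {
    last_followup_date <- max_observed_date(lesions, ca125, treatment_lines,
                                            death_date, therapy_change_dates)
  } else {
    last_followup_date <- parse_iso_date(last_followup_date)
  }
  # samples strictly ordered by date after ingestion
  ca125 <- ca125[order(ca125$sample_date), , drop = FALSE]
  rownames(ca125) <- NULL
  treatment_lines <- treatment_lines[order(treatment_lines$start_date), ,
                                     drop = FALSE]
  rownames(treatment_lines) <- NULL
  lesions <- lesions[order(lesions$lesion_id, lesions$timepoint_date), ,
                     drop = FALSE]
  rownames(lesions) <- NULL

  pc <- structure(list(
    patient_id = as.character(patient_id),
    uln_u_per_ml = uln_u_per_ml,
    setting = setting,
    lesions = lesions[, LESION_COLS],
    ca125 = ca125[, CA125_COLS, drop = FALSE],
    treatment_lines = treatment_lines[, LINE_COLS, drop = FALSE],
    death_date = death_date,
    therapy_change_dates = therapy_change_dates,
    last_followup_date = last_followup_date
  ), class = "patient_course")
  problems <- validate_patient_course(pc)
  if (length(problems) > 0)
    stopf("invalid patient course '%s': %s", patient_id,
          paste(problems, collapse = "; "))
  pc
}

max_observed_date <- function(lesions, ca125, treatment_lines, death_date,
                              therapy_change_dates) {
  d <- c(lesions$timepoint_date, ca125$sample_date,
         treatment_lines$start_date, treatment_lines$end_date,
         death_date, therapy_change_dates)
  d <- d[!is.na(d)]
  if (length(d) == 0) as.Date(NA) else max(d)
}

#' Validate a patient course against its invariants
#'
#' Checks the domain invariants: non-negative diameters, non-negative lesion
#' iodine, strictly positive aortic iodine, positive CA125 values and ULN,
#' strictly increasing CA125 sample dates, non-overlapping ordered treatment
#' lines, and no measurement dated after death or last follow-up.
#'
#' @param pc A `patient_course`.
#' @return Character vector of human-readable problems (empty when valid).
#' @export
validate_patient_course <- function(pc) {
  p <- character()
  les <- pc$lesions
  if (any(is.na(les$timepoint_date)))
    p <- c(p, "lesion timepoint_date unparseable or missing")
  if (any(!is.na(les$longest_diameter_mm) & les$longest_diameter_mm < 0))
    p <- c(p, "longest_diameter_mm must be >= 0 (0 encodes disappearance)")
  if (any(!is.na(les$iodine_mg_per_ml) & les$iodine_mg_per_ml < 0))
    p <- c(p, "iodine_mg_per_ml must be >= 0")
  if (any(!is.na(les$aortic_iodine_mg_per_ml) & les$aortic_iodine_mg_per_ml <= 0))
    p <- c(p, "aortic_iodine_mg_per_ml must be > 0")
  if (anyDuplicated(les[, c("lesion_id", "timepoint_date")]))
    p <- c(p, "duplicate (lesion_id, timepoint_date) measurement")
  if (!is.numeric(pc$uln_u_per_ml) || is.na(pc$uln_u_per_ml) ||
      pc$uln_u_per_ml <= 0)
    p <- c(p, "uln_u_per_ml must be > 0")
  ca <- pc$ca125
  if (any(is.na(ca$sample_date)))
    p <- c(p, "CA125 sample_date unparseable or missing")
  if (any(!is.na(ca$value_u_per_ml) & ca$value_u_per_ml <= 0) ||
      any(is.na(ca$value_u_per_ml)))
    p <- c(p, "CA125 value_u_per_ml must be > 0")
  if (nrow(ca) > 1 && any(duplicated(ca$sample_date)))
    p <- c(p, "CA125 sample dates must be unique within a patient")
  tl <- pc$treatment_lines
  if (nrow(tl) > 1) {
    if (is.unsorted(tl$start_date, strictly = TRUE))
      p <- c(p, "treatment lines must be strictly ordered by start_date")
    ends <- tl$end_date[-nrow(tl)]
    starts <- tl$start_date[-1]
    if (any(!is.na(ends) & ends > starts))
      p <- c(p, "treatment lines overlap")
  }
  horizon <- min_date(pc$last_followup_date, pc$death_date)
  if (!is.na(horizon)) {
    dates <- c(les$timepoint_date, ca$sample_date)
    if (any(!is.na(dates) & dates > horizon))
      p <- c(p, "measurement dated after death/last follow-up")
  }
  p
}

#' Bundle patient courses into a cohort
#'
#' @param courses List of `patient_course` objects.
#' @return A `patient_cohort` (a named list of courses).
#' @export
patient_cohort <- function(courses = list()) {
  stopifnot(all(vapply(courses, inherits, logical(1), "patient_course")))
  ids <- vapply(courses, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids)) stopf("duplicate patient_id in cohort")
  names(courses) <- ids
  structure(courses, class = "patient_cohort")
}

#' @export
print.patient_cohort <- function(x, ...) {
  n_les <- sum(vapply(x, function(pc) nrow(pc$lesions), integer(1)))
  cat(sprintf("<patient_cohort> %d patients, %d lesion measurements\n",
              length(x), n_les))
  invisible(x)
}

#' @export
print.patient_course <- function(x, ...) {
  cat(sprintf("<patient_course> %s: %d lesion rows, %d CA125 samples, %d lines\n",
              x$patient_id, nrow(x$lesions), nrow(x$ca125),
              nrow(x$treatment_lines)))
  invisible(x)
}

# Imaging timepoints (unique, sorted) for a course.
imaging_timepoints <- function(pc) sort(unique(pc$lesions$timepoint_date))

# Number of distinct imaging timepoints with at least one iodine measurement.
n_iodine_timepoints <- function(pc) {
  les <- pc$lesions
  length(unique(les$timepoint_date[!is.na(les$iodine_mg_per_ml)]))
}

#' Filter a cohort to DECT-evaluable patients
#'
#' A patient is DECT-evaluable only with at least `min_iodine_timepoints`
#' distinct imaging timepoints carrying iodine measurements (a single scan
#' supports no change assessment). Mirrors the triage applied to the source
#' cohort before analysis.
#'
#' @param cohort A `patient_cohort`.
#' @param min_iodine_timepoints Minimum number of iodine-bearing timepoints
#'   (default 2).
#' @return List with `evaluable` (a `patient_cohort`) and `report`, a
#'   data.frame of excluded patients and reasons plus counts in attributes.
#' @export
eligibility_filter <- function(cohort, min_iodine_timepoints = 2) {
  n_tp <- vapply(cohort, n_iodine_timepoints, integer(1))
  keep <- n_tp >= min_iodine_timepoints
  report <- data.frame(
    patient_id = vapply(cohort[!keep], `[[`, character(1), "patient_id"),
    reason = sprintf("only %d DECT scan(s) with iodine measurements (< %d)",
                     n_tp[!keep], min_iodine_timepoints),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(evaluable = patient_cohort(unname(cohort[keep])),
              report = report)
  attr(out$report, "n_input") <- length(cohort)
  attr(out$report, "n_evaluable") <- sum(keep)
  attr(out$report, "n_excluded") <- sum(!keep)
  out
}
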