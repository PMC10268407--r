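# Orchestration: run the three criteria engines over whole patient courses
# and cohorts, producing per-timepoint classification streams and per-line
# summaries, then survival records per criterion.
#
# Baseline for an imaging criterion is the latest scan on or before the
# treatment line start; every later scan inside the line window (before the
# next line starts) is classified pairwise against that baseline, so
# mid-treatment scans can trigger progression. The per-line category is
# taken from the last scan of the line; the progression date is the first
# scan classified PD.

line_window_end <- function(course, line) {
  tl <- course$treatment_lines
  later <- tl$start_date[tl$start_date > line$start_date]
  if (length(later) > 0) min(later) else structure(Inf, class = "Date")
}

classification_row <- function(course, line, criterion, date, cls) {
  data.frame(patient_id = course$patient_id, line_index = line$line_index,
             criterion = criterion, timepoint_date = date,
             category = cls$category,
             percent_change = cls$percent_change %||% NA_real_,
             responder = if (is.null(cls$responder)) NA else cls$responder,
             detail = cls$detail, stringsAsFactors = FALSE)
}

ne_summary <- function(course, line, criterion, detail) {
  data.frame(patient_id = course$patient_id, line_index = line$line_index,
             criterion = criterion, category = "NE",
             percent_change = NA_real_, responder = NA,
             assessment_date = as.Date(NA), progression_date = as.Date(NA),
             detail = detail, stringsAsFactors = FALSE)
}

# Values (diameter or normalized iodine) for a lesion set at one timepoint.
lesion_values_at <- function(les, ids, date, what = c("diameter", "iodine"),
                             normalized = TRUE, fallback_raw = FALSE) {
  what <- match.arg(what)
  sel <- les[les$timepoint_date == date & les$lesion_id %in% ids, ,
             drop = FALSE]
  sel <- sel[match(ids, sel$lesion_id), , drop = FALSE]  # NA row if absent
  if (what == "diameter") return(sel$longest_diameter_mm)
  if (!normalized) return(sel$iodine_mg_per_ml)
  normalize_iodine(sel$iodine_mg_per_ml, sel$aortic_iodine_mg_per_ml,
                   fallback_raw = fallback_raw)
}

#' Classify one treatment line of a course by an imaging criterion
#'
#' @param course A `patient_course`.
#' @param line One-row data.frame from `course$treatment_lines` (default:
#'   first line).
#' @param criterion `"recist"` (sum of longest diameters) or `"dect"`
#'   (aggregated aortic-normalized iodine concentration).
#' @param threshold_percent DECT classification boundary (default 15).
#' @param aggregate DECT multi-lesion aggregation, `"sum"` or `"mean"`.
#' @param normalized Normalize iodine to the aorta (default `TRUE`); set
#'   `FALSE` to work on raw mg/mL values.
#' @param fallback_raw Fall back to raw iodine when the aortic value is
#'   missing (default `FALSE`).
#' @param carry_forward Carry a lesion's last observed diameter forward when
#'   it is unmeasured at a follow-up (default `FALSE`: such a timepoint is
#'   NE, because silent imputation hides data errors).
#' @param pd_reference RECIST progression reference, `"baseline"` or
#'   `"nadir"` (strict RECIST 1.1: nadir + 20% and >= 5 mm absolute).
#' @return List: `timepoints` (one row per follow-up scan) and `summary`
#'   (one row for the line).
#' @export
classify_imaging_course <- function(course, line = NULL,
                                    criterion = c("recist", "dect"),
                                    threshold_percent = 15,
                                    aggregate = c("sum", "mean"),
                                    normalized = TRUE, fallback_raw = FALSE,
                                    carry_forward = FALSE,
                                    pd_reference = c("baseline", "nadir")) {
  criterion <- match.arg(criterion)
  aggregate <- match.arg(aggregate)
  pd_reference <- match.arg(pd_reference)
  if (is.null(line)) line <- course$treatment_lines[1, , drop = FALSE]
  crit_label <- toupper(criterion)
  les <- course$lesions
  if (criterion == "dect") les <- les[!is.na(les$iodine_mg_per_ml), ,
                                      drop = FALSE]
  tps <- sort(unique(les$timepoint_date))
  base_tp <- tps[tps <= line$start_date]
  if (length(base_tp) == 0)
    return(list(timepoints = NULL,
                summary = ne_summary(course, line, crit_label,
                                     "no baseline scan on or before treatment start")))
  base_tp <- max(base_tp)
  followups <- tps[tps > base_tp & tps < line_window_end(course, line)]
  if (length(followups) == 0)
    return(list(timepoints = NULL,
                summary = ne_summary(course, line, crit_label,
                                     "no follow-up scan within the treatment line")))
  ids <- unique(les$lesion_id[les$timepoint_date == base_tp])
  base_vals <- lesion_values_at(les, ids, base_tp,
                                if (criterion == "recist") "diameter" else "iodine",
                                normalized, fallback_raw)
  base_agg <- tryCatch(
    if (criterion == "recist") compute_sld(base_vals)
    else aggregate_iodine(base_vals, aggregate),
    error = function(e) NA_real_)
  if (is.na(base_agg) || base_agg <= 0)
    return(list(timepoints = NULL,
                summary = ne_summary(course, line, crit_label,
                                     "baseline aggregate not positive or not evaluable")))
  last_vals <- base_vals
  nadir_agg <- base_agg
  rows <- vector("list", length(followups))
  for (k in seq_along(followups)) {
    tp <- followups[k]
    vals <- lesion_values_at(les, ids, tp,
                             if (criterion == "recist") "diameter" else "iodine",
                             normalized, fallback_raw)
    if (any(is.na(vals)) && carry_forward) {
      vals[is.na(vals)] <- last_vals[is.na(vals)]
    }
    new_ids <- setdiff(unique(les$lesion_id[les$timepoint_date == tp &
                                              les$longest_diameter_mm > 0]),
                       ids)
    cls <- if (any(is.na(vals))) {
      list(category = "NE", percent_change = NA_real_, responder = NA,
           detail = "target lesion unmeasured at follow-up (carry-forward off)")
    } else if (criterion == "recist") {
      classify_recist(base_agg, compute_sld(vals),
                      new_lesions = length(new_ids) > 0,
                      pd_reference = pd_reference, nadir_sld_mm = nadir_agg)
    } else {
      classify_dect(base_agg, aggregate_iodine(vals, aggregate),
                    threshold_percent)
    }
    if (!any(is.na(vals))) {
      agg <- if (criterion == "recist") compute_sld(vals)
        else aggregate_iodine(vals, aggregate)
      nadir_agg <- min(nadir_agg, agg)
      last_vals <- vals
    }
    rows[[k]] <- classification_row(course, line, crit_label, tp, cls)
  }
  timepoints <- do.call(rbind, rows)
  pd_dates <- timepoints$timepoint_date[timepoints$category == "PD"]
  last <- timepoints[nrow(timepoints), ]
  summary <- data.frame(
    patient_id = course$patient_id, line_index = line$line_index,
    criterion = crit_label, category = last$category,
    percent_change = last$percent_change, responder = last$responder,
    assessment_date = last$timepoint_date,
    progression_date = if (length(pd_dates) > 0) min(pd_dates) else as.Date(NA),
    detail = last$detail, stringsAsFactors = FALSE)
  list(timepoints = timepoints, summary = summary)
}

#' Classify a whole cohort under the three criteria
#'
#' Runs the RECIST, DECT and GCIG CA125 engines over every patient (first
#' treatment line by default, or all lines) and returns the per-timepoint
#' classification stream plus the per-line summary consumed by the survival
#' and concordance stages.
#'
#' @param cohort A `patient_cohort`.
#' @param criteria Subset of `c("recist", "dect", "ca125")`.
#' @param lines `"first"` (default) or `"all"`.
#' @param ... Passed to [classify_imaging_course()] and [classify_gcig()]
#'   (e.g. `threshold_percent`, `aggregate`, `normalized`, `carry_forward`).
#' @return List: `timepoints` data.frame, `summary` data.frame (one row per
#'   patient x line x criterion).
#' @export
classify_cohort <- function(cohort, criteria = c("recist", "dect", "ca125"),
                            lines = c("first", "all"), ...) {
  lines <- match.arg(lines)
  criteria <- match.arg(criteria, several.ok = TRUE)
  dots <- list(...)
  imaging_args <- dots[names(dots) %in%
                         names(formals(classify_imaging_course))]
  gcig_args <- dots[names(dots) %in% names(formals(classify_gcig))]
  tp_rows <- list(); sm_rows <- list()
  for (pc in cohort) {
    tl <- pc$treatment_lines
    if (nrow(tl) == 0) next
    line_idx <- if (lines == "first") 1 else seq_len(nrow(tl))
    for (li in line_idx) {
      line <- tl[li, , drop = FALSE]
      for (cr in criteria) {
        if (cr == "ca125") {
          sm <- do.call(classify_gcig, c(list(course = pc, line = line),
                                         gcig_args))
          sm_rows[[length(sm_rows) + 1]] <- sm
        } else {
          out <- do.call(classify_imaging_course,
                         c(list(course = pc, line = line, criterion = cr),
                           imaging_args))
          if (!is.null(out$timepoints))
            tp_rows[[length(tp_rows) + 1]] <- out$timepoints
          sm_rows[[length(sm_rows) + 1]] <- out$summary
        }
      }
    }
  }
  list(timepoints = if (length(tp_rows) > 0) do.call(rbind, tp_rows) else NULL,
       summary = rbind_rows(sm_rows))
}

#' Build survival records for one criterion
#'
#' Joins the per-line classification summary with the cohort's outcome dates
#' to derive progression-free survival per patient: time from treatment
#' start to the criterion's first progression date, censored at the earliest
#' of last follow-up, death and next treatment line. Patients NE under the
#' criterion are dropped. The survival comparison defaults to the relapse
#' subset, matching the analysis population the criteria were developed on.
#'
#' @param summary Per-line classification summary ([classify_cohort()]),
#'   after any [reclassify_nonresponders()] override.
#' @param cohort The `patient_cohort`.
#' @param criterion `"RECIST"`, `"DECT"` or `"CA125"`.
#' @param subset `"relapse"` (default) or `"all"`.
#' @param death_is_event Count death as a PFS event (default `TRUE`).
#' @return data.frame: `patient_id`, `criterion`, `time_months`, `event`,
#'   `responder`.
#' @export
survival_records <- function(summary, cohort, criterion,
                             subset = c("relapse", "all"),
                             death_is_event = TRUE) {
  subset <- match.arg(subset)
  criterion <- toupper(criterion)
  sm <- summary[summary$criterion == criterion & summary$category != "NE" &
                  !is.na(summary$responder), , drop = FALSE]
  rows <- lapply(seq_len(nrow(sm)), function(i) {
    pc <- cohort[[sm$patient_id[i]]]
    if (subset == "relapse" && pc$setting != "relapse") return(NULL)
    tl <- pc$treatment_lines
    line <- tl[tl$line_index == sm$line_index[i], , drop = FALSE]
    nxt <- tl$start_date[tl$start_date > line$start_date]
    pfs <- derive_pfs(line$start_date,
                      progression_date = sm$progression_date[i],
                      death_date = pc$death_date,
                      last_followup_date = pc$last_followup_date,
                      next_line_start = if (length(nxt) > 0) min(nxt) else NULL,
                      death_is_event = death_is_event)
    data.frame(patient_id = sm$patient_id[i], criterion = criterion,
               time_months = pfs$time_months, event = pfs$event,
               responder = sm$responder[i], stringsAsFactors = FALSE)
  })
  rbind_rows(rows) %||%
    data.frame(patient_id = character(), criterion = character(),
               time_months = numeric(), event = logical(),
               responder = logical())
}

#' Compare responder vs non-responder survival
#'
#' Kaplan-Meier medians per group, the log-rank test, and the
#' Mantel-Haenszel hazard ratio (responders relative to non-responders).
#' P-values are reported to four decimals; no multiple-testing correction is
#' applied.
#'
#' @param records data.frame from [survival_records()].
#' @param ... Passed to [logrank_test()] and [hazard_ratio()] (e.g.
#'   `method`).
#' @return List: `n_responder`, `n_nonresponder`, `median_responder`,
#'   `median_nonresponder`, `chisq`, `p`, `hr`, `ci_lower`, `ci_upper`.
#' @export
compare_survival <- function(records, ...) {
  r <- records[records$responder, , drop = FALSE]
  nr <- records[!records$responder, , drop = FALSE]
  if (nrow(r) == 0 || nrow(nr) == 0)
    stopf("both responder and non-responder groups must be non-empty")
  km_r <- km_curve(r$time_months, r$event)
  km_nr <- km_curve(nr$time_months, nr$event)
  lr <- logrank_test(r$time_months, r$event, nr$time_months, nr$event)
  hr <- hazard_ratio(r$time_months, r$event, nr$time_months, nr$event)
  list(n_responder = nrow(r), n_nonresponder = nrow(nr),
       median_responder = km_r$median, median_nonresponder = km_nr$median,
       chisq = lr$chisq, p = round(lr$p, 4), hr = hr$hr,
       ci_lower = hr$ci_lower, ci_upper = hr$ci_upper,
       km_responder = km_r, km_nonresponder = km_nr)
}
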