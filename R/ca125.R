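# GCIG CA125 response/progression rules: eligibility gating (pre-treatment
# value at least twice the ULN), 50% response maintained >= 28 days, and
# progression to twice the nadir (or twice the ULN for patients whose marker
# normalized) confirmed on two samples at least a week apart.

#' CA125 eligibility gate and pre-treatment value
#'
#' A patient is evaluable by the GCIG CA125 criteria only when the
#' pre-treatment sample is elevated to at least twice the upper limit of
#' normal. The pre-treatment value is the latest sample taken on or before
#' treatment start within `window_days`.
#'
#' @param dates,values CA125 sample dates (Date) and values (U/mL), sorted.
#' @param treatment_start Treatment line start date.
#' @param uln Assay upper limit of normal (U/mL).
#' @param window_days Maximum age of the pre-treatment sample (default 14).
#' @return List: `evaluable`, `pretreatment_value`, `pretreatment_date`,
#'   `reason` (when not evaluable).
#' @export
ca125_eligibility <- function(dates, values, treatment_start, uln = 35,
                              window_days = 14) {
  pre <- which(dates <= treatment_start &
                 dates >= treatment_start - window_days)
  if (length(pre) == 0)
    return(list(evaluable = FALSE, pretreatment_value = NA_real_,
                pretreatment_date = as.Date(NA),
                reason = sprintf("no CA125 sample within %d days before treatment start",
                                 window_days)))
  i <- pre[length(pre)]
  ok <- values[i] >= 2 * uln
  list(evaluable = ok, pretreatment_value = values[i],
       pretreatment_date = dates[i],
       reason = if (ok) NA_character_ else
         sprintf("pre-treatment CA125 %.1f < 2 x ULN (%.1f)", values[i], 2 * uln))
}

#' GCIG CA125 response rule
#'
#' Response requires a post-treatment sample at or below half the
#' pre-treatment value, confirmed by a later sample (>= `confirm_days` later)
#' also at or below half the pre-treatment value, with no intervening sample
#' above that level. The response date is the first qualifying sample.
#'
#' @inheritParams ca125_eligibility
#' @param pretreatment Pre-treatment CA125 value (U/mL).
#' @param confirm_days Confirmation window (default 28 days).
#' @return List: `responded`, `response_date`.
#' @export
ca125_response <- function(dates, values, treatment_start, pretreatment,
                           confirm_days = 28) {
  post <- which(dates > treatment_start)
  half <- 0.5 * pretreatment
  for (a in seq_along(post)) {
    i <- post[a]
    if (values[i] > half) next
    if (a == length(post)) break
    for (b in seq(a + 1, length(post))) {
      j <- post[b]
      if (values[j] > half) break      # intervening breach: this s1 fails
      if (as.numeric(dates[j] - dates[i]) >= confirm_days)
        return(list(responded = TRUE, response_date = dates[i]))
    }
  }
  list(responded = FALSE, response_date = as.Date(NA))
}

#' GCIG CA125 progression rule
#'
#' The running nadir is the minimum of the pre-treatment value and all
#' post-treatment samples seen so far. Patients whose CA125 normalized
#' (nadir at or below the ULN) progress at twice the ULN; patients who never
#' normalized progress at twice the nadir. Progression requires two samples
#' at or above the threshold at least `confirm_gap_days` apart (the threshold
#' is frozen at the first qualifying sample); the progression date is the
#' first of the two.
#'
#' @inheritParams ca125_response
#' @param confirm_gap_days Minimum gap between the two confirming samples
#'   (default 7 days).
#' @return List: `progressed`, `progression_date`, `nadir`.
#' @export
ca125_progression <- function(dates, values, treatment_start, uln = 35,
                              pretreatment = NULL, confirm_gap_days = 7) {
  post <- which(dates > treatment_start)
  vals <- values[post]
  dts <- dates[post]
  n <- length(post)
  nadir0 <- if (is.null(pretreatment) || is.na(pretreatment)) Inf
    else pretreatment
  running_nadir <- if (n > 0) pmin(nadir0, cummin(vals)) else numeric()
  final_nadir <- if (n > 0) running_nadir[n]
    else if (is.finite(nadir0)) nadir0 else NA_real_
  if (n < 2)
    return(list(progressed = FALSE, progression_date = as.Date(NA),
                nadir = final_nadir))
  for (i in seq_len(n - 1)) {
    nad <- running_nadir[i]
    thr <- if (nad <= uln) 2 * uln else 2 * nad
    if (vals[i] < thr) next
    for (j in seq(i + 1, n)) {
      if (vals[j] >= thr && as.numeric(dts[j] - dts[i]) >= confirm_gap_days)
        # threshold was frozen at sample i, but the reported nadir is the
        # series-wide running minimum (the Ca125Assessment contract)
        return(list(progressed = TRUE, progression_date = dts[i],
                    nadir = final_nadir))
    }
  }
  list(progressed = FALSE, progression_date = as.Date(NA),
       nadir = final_nadir)
}

#' Classify a treatment line by the GCIG CA125 criteria
#'
#' Composition of the eligibility, response and progression rules for one
#' treatment line of one patient: NE when the eligibility gate fails or
#' follow-up sampling is shorter than `min_followup_days`; PD when
#' progression fires before (or without) response; PR when response fires
#' first (CR and PR are not distinguished: a normalized-CA125 flag is carried
#' in `detail` instead); SD otherwise. A progression date occurring after a
#' response is retained for progression-free survival.
#'
#' @param course A `patient_course`.
#' @param line One-row data.frame from `course$treatment_lines` (default:
#'   first line).
#' @param uln Override the course ULN.
#' @param window_days Pre-treatment sample window (days).
#' @param min_followup_days Minimum post-treatment sampling span for an SD
#'   call (default 28).
#' @return One-row data.frame: `patient_id`, `line_index`, `criterion`,
#'   `category`, `percent_change`, `responder`, `assessment_date`,
#'   `progression_date`, `detail`.
#' @export
classify_gcig <- function(course, line = NULL, uln = NULL, window_days = 14,
                          min_followup_days = 28) {
  if (is.null(line)) line <- course$treatment_lines[1, , drop = FALSE]
  if (is.null(uln)) uln <- course$uln_u_per_ml
  start <- line$start_date
  dates <- course$ca125$sample_date
  values <- course$ca125$value_u_per_ml
  row <- function(category, pc, assess, prog_date, detail) {
    data.frame(patient_id = course$patient_id,
               line_index = line$line_index,
               criterion = "CA125", category = category,
               percent_change = pc,
               responder = if (category == "NE") NA else
                 category %in% c("CR", "PR", "SD"),
               assessment_date = assess,
               progression_date = prog_date,
               detail = detail, stringsAsFactors = FALSE)
  }
  elig <- ca125_eligibility(dates, values, start, uln, window_days)
  if (!elig$evaluable)
    return(row("NE", NA_real_, as.Date(NA), as.Date(NA), elig$reason))
  pre <- elig$pretreatment_value
  resp <- ca125_response(dates, values, start, pre)
  prog <- ca125_progression(dates, values, start, uln, pre)
  post <- which(dates > start)
  pc_final <- if (length(post) > 0)
    percent_change(pre, values[post[length(post)]]) else NA_real_
  if (prog$progressed &&
      (!resp$responded || prog$progression_date <= resp$response_date))
    return(row("PD", pc_final, prog$progression_date, prog$progression_date,
               sprintf("CA125 rose to >= 2 x %s, confirmed >= 7 d apart",
                       if (prog$nadir <= uln) "ULN" else "nadir")))
  if (resp$responded)
    return(row("PR", pc_final, resp$response_date, prog$progression_date,
               sprintf(">= 50%% fall from pre-treatment %.1f maintained >= 28 d%s",
                       pre,
                       if (!is.na(prog$nadir) && prog$nadir <= uln)
                         " (CA125 normalized)" else "")))
  span <- if (length(post) > 0)
    as.numeric(dates[post[length(post)]] - start) else 0
  if (span >= min_followup_days)
    return(row("SD", pc_final, dates[post[length(post)]], as.Date(NA),
               "evaluable; neither response nor progression fired"))
  row("NE", NA_real_, as.Date(NA), as.Date(NA),
      sprintf("post-treatment CA125 follow-up %d d < %d d", span,
              min_followup_days))
}
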