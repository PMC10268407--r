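# RECIST 1.1 size-based response classification from the sum of longest
# diameters (SLD) of target lesions.

#' Sum of longest diameters at one timepoint
#'
#' @param diameters_mm Numeric vector of per-lesion longest diameters (mm) at
#'   a single imaging timepoint. A value of 0 means the lesion disappeared.
#' @return The arithmetic sum (mm).
#' @export
compute_sld <- function(diameters_mm) {
  if (length(diameters_mm) == 0 || all(is.na(diameters_mm)))
    stopf("no lesion measurements at timepoint: SLD not evaluable")
  if (any(is.na(diameters_mm)))
    stopf("missing lesion diameter at timepoint: SLD not evaluable (enable carry-forward or record disappearance as 0)")
  if (any(diameters_mm < 0)) stopf("negative diameter")
  sum(diameters_mm)
}

#' Percent change from baseline
#'
#' `100 * (followup - baseline) / baseline`, full precision retained;
#' reporting layers round half away from zero to one decimal.
#'
#' @param baseline Positive baseline scalar (or vector).
#' @param followup Non-negative follow-up value(s).
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(29.8, 35)  # +17.449...
#' percent_change(1.4, 1.1)  # -21.428...
percent_change <- function(baseline, followup) {
  if (any(is.na(baseline)) || any(baseline <= 0))
    stopf("percent change undefined: baseline must be > 0")
  100 * (followup - baseline) / baseline
}

#' Classify response from an SLD assessment
#'
#' Default rules (thresholds inclusive, both referenced to BASELINE):
#' new lesions force PD; follow-up SLD of 0 with no new lesions is CR;
#' a decrease of at least 30% is PR; an increase of at least 20% is PD;
#' anything else is SD. `pd_reference = "nadir"` switches progression to the
#' strict RECIST 1.1 rule: at least 20% increase over the smallest SLD seen
#' so far AND an absolute increase of at least 5 mm over it.
#'
#' @param baseline_sld_mm Baseline SLD (mm).
#' @param followup_sld_mm Follow-up SLD (mm).
#' @param new_lesions Any new or unequivocally enlarging non-target lesion?
#' @param pd_reference `"baseline"` (default) or `"nadir"` (strict RECIST 1.1).
#' @param nadir_sld_mm Smallest SLD observed up to this assessment; required
#'   for `pd_reference = "nadir"`.
#' @return List with `category` (`"CR"`, `"PR"`, `"SD"`, `"PD"`, or `"NE"`),
#'   `percent_change`, `responder` (`TRUE` for CR/PR/SD, `NA` for NE) and
#'   `detail` (the rule that fired).
#' @export
classify_recist <- function(baseline_sld_mm, followup_sld_mm,
                            new_lesions = FALSE,
                            pd_reference = c("baseline", "nadir"),
                            nadir_sld_mm = NULL) {
  pd_reference <- match.arg(pd_reference)
  res <- function(category, pc, detail) {
    list(category = category, percent_change = pc,
         responder = if (category == "NE") NA else category != "PD",
         detail = detail)
  }
  if (isTRUE(new_lesions))
    return(res("PD", if (!is.na(baseline_sld_mm) && baseline_sld_mm > 0)
      percent_change(baseline_sld_mm, followup_sld_mm) else NA_real_,
      "new lesions on follow-up imaging"))
  if (is.na(baseline_sld_mm) || is.na(followup_sld_mm))
    return(res("NE", NA_real_, "missing SLD"))
  if (baseline_sld_mm == 0 && followup_sld_mm == 0)
    return(res("CR", NA_real_, "all lesions absent at baseline and follow-up"))
  if (baseline_sld_mm <= 0)
    return(res("NE", NA_real_, "baseline SLD not positive: percent change undefined"))
  pc <- percent_change(baseline_sld_mm, followup_sld_mm)
  if (followup_sld_mm == 0)
    return(res("CR", pc, "complete disappearance of all lesions"))
  if (pc <= -30)
    return(res("PR", pc, sprintf("SLD decrease %.1f%% >= 30%%", -pc)))
  pd <- if (pd_reference == "baseline") pc >= 20 else {
    if (is.null(nadir_sld_mm) || is.na(nadir_sld_mm) || nadir_sld_mm <= 0)
      stopf("nadir_sld_mm required for pd_reference = 'nadir'")
    percent_change(nadir_sld_mm, followup_sld_mm) >= 20 &&
      (followup_sld_mm - nadir_sld_mm) >= 5
  }
  if (pd)
    return(res("PD", pc, sprintf("SLD increase %.1f%% >= 20%% (%s reference)",
                                 pc, pd_reference)))
  res("SD", pc, "neither PR nor PD")
}
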