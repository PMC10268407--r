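# Dual-energy CT iodine-concentration response criterion: aortic
# normalization, percent change of the aggregated lesion iodine, a +/-15%
# classification boundary with the any-decrease responder rule, and the
# 10/15/20% threshold sweep used to pick the boundary on a training cohort.

#' Normalize lesion iodine concentration to the aorta
#'
#' Contrast delivery varies between scans; dividing the lesion iodine
#' concentration by the aortic iodine concentration measured on the same scan
#' (at the level of the diaphragm) yields a dimensionless ratio comparable
#' across timepoints.
#'
#' @param lesion_iodine Lesion iodine concentration(s), mg/mL, >= 0.
#' @param aortic_iodine Aortic iodine concentration(s), mg/mL, > 0.
#' @param fallback_raw If `TRUE`, a missing aortic value falls back to the
#'   raw lesion value; the returned vector then carries an `unnormalized`
#'   attribute flagging those entries.
#' @return Numeric vector of normalized ratios (or flagged raw values).
#' @export
normalize_iodine <- function(lesion_iodine, aortic_iodine,
                             fallback_raw = FALSE) {
  if (any(!is.na(lesion_iodine) & lesion_iodine < 0))
    stopf("lesion iodine must be >= 0")
  if (any(!is.na(aortic_iodine) & aortic_iodine <= 0))
    stopf("aortic iodine must be > 0")
  miss <- is.na(aortic_iodine)
  if (any(miss) && !fallback_raw)
    stopf("aortic iodine missing and fallback_raw = FALSE")
  out <- lesion_iodine / aortic_iodine
  if (any(miss)) {
    out[miss] <- lesion_iodine[miss]
    attr(out, "unnormalized") <- miss
  }
  out
}

#' Aggregate per-lesion iodine at one timepoint
#'
#' The multi-lesion aggregate mirrors the sum-of-longest-diameters
#' convention: the default is the sum of per-lesion (normalized) iodine over
#' target lesions; `mode = "mean"` averages instead.
#'
#' @param values Per-lesion iodine values at one timepoint.
#' @param mode `"sum"` (default) or `"mean"`.
#' @return Scalar aggregate.
#' @export
aggregate_iodine <- function(values, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (length(values) == 0 || all(is.na(values)))
    stopf("no iodine-bearing lesions at timepoint")
  if (any(is.na(values)))
    stopf("missing iodine value for a target lesion at timepoint")
  if (mode == "sum") sum(values) else mean(values)
}

#' Classify response from the iodine-concentration change
#'
#' With threshold theta (percent, default 15): an increase of at least theta
#' is PD, a decrease of at least theta is PR, anything in between is SD.
#' Boundaries are inclusive. Responder status is `category != "PD"`; the
#' observation that any decrease in iodine concentration tracked clinical
#' improvement is surfaced as the `any_decrease` flag, not as a category.
#'
#' @param baseline_agg Positive baseline aggregate iodine.
#' @param followup_agg Non-negative follow-up aggregate iodine.
#' @param threshold_percent Classification boundary theta > 0 (default 15).
#' @return List: `category` (`"PR"`/`"SD"`/`"PD"`), `responder`,
#'   `percent_change`, `any_decrease`, `detail`.
#' @export
classify_dect <- function(baseline_agg, followup_agg, threshold_percent = 15) {
  if (!is.numeric(threshold_percent) || threshold_percent <= 0)
    stopf("threshold_percent must be > 0")
  pc <- percent_change(baseline_agg, followup_agg)
  category <- if (pc >= threshold_percent) "PD"
    else if (pc <= -threshold_percent) "PR" else "SD"
  list(category = category, responder = category != "PD",
       percent_change = pc, any_decrease = pc < 0,
       detail = sprintf("iodine change %+.1f%% vs +/-%g%% boundary", pc,
                        threshold_percent))
}

#' Sweep the iodine classification threshold against reference labels
#'
#' Re-classifies every patient's iodine percent change at each candidate
#' threshold and tabulates agreement with a reference non-responder label
#' (e.g. GCIG CA125 progression and/or clinical outcome): accuracy,
#' sensitivity and specificity for detecting non-responders (PD calls), and
#' balanced accuracy. The selected threshold maximizes balanced accuracy;
#' ties break toward the larger threshold (the more conservative PD rule).
#'
#' @param percent_changes Per-patient iodine percent change from baseline.
#' @param reference_nonresponder Logical vector: reference label per patient
#'   (`TRUE` = non-responder).
#' @param thresholds Candidate thresholds in percent (default 10, 15, 20).
#' @return List: `table` (one row per threshold) and `selected`.
#' @export
threshold_sweep <- function(percent_changes, reference_nonresponder,
                            thresholds = c(10, 15, 20)) {
  keep <- !is.na(percent_changes) & !is.na(reference_nonresponder)
  pc <- percent_changes[keep]
  ref <- reference_nonresponder[keep]
  if (length(pc) == 0) stopf("no reference labels available for sweep")
  rows <- lapply(thresholds, function(th) {
    pred_pd <- pc >= th
    tp <- sum(pred_pd & ref); fn <- sum(!pred_pd & ref)
    tn <- sum(!pred_pd & !ref); fp <- sum(pred_pd & !ref)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    data.frame(threshold = th, n = length(pc),
               n_pd_calls = sum(pred_pd),
               n_pr_calls = sum(pc <= -th),
               accuracy = (tp + tn) / length(pc),
               sensitivity = sens, specificity = spec,
               balanced_accuracy = mean(c(sens, spec), na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  best <- max(tab$balanced_accuracy)
  selected <- max(tab$threshold[tab$balanced_accuracy >= best - 1e-12])
  list(table = tab, selected = selected)
}
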