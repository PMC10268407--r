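# Progression-free survival derivation and the responder vs non-responder
# comparison: Kaplan-Meier product-limit curves, the one-degree-of-freedom
# log-rank test (conditional hypergeometric variance for ties, with an exact
# permutation mode for small samples), Mantel-Haenszel O/E hazard ratios
# (matching common Prism output), and cross-criterion concordance tables.

#' Derive a progression-free survival record for one treatment line
#'
#' Time runs from treatment initiation to the first progression date under
#' the criterion at hand; without progression the patient is censored at the
#' earliest of last follow-up, death and the start of the next treatment
#' line. Death before that censoring bound counts as a PFS event by default
#' (progression-free survival convention); set `death_is_event = FALSE` to
#' censor at death instead. Times are reported in months (days / 30.4375).
#'
#' @param line_start Treatment line start date.
#' @param progression_date First progression date under the criterion, or
#'   `NA`/`NULL` if none was observed.
#' @param death_date Death date or `NA`.
#' @param last_followup_date Last follow-up date.
#' @param next_line_start Start of the following treatment line, or `NA`.
#' @param death_is_event Count death as an event (default `TRUE`).
#' @return List: `time_months`, `event` (logical), `event_date`.
#' @export
derive_pfs <- function(line_start, progression_date = NULL,
                       death_date = NULL, last_followup_date,
                       next_line_start = NULL, death_is_event = TRUE) {
  if (is.null(line_start) || is.na(line_start))
    stopf("treatment line start date missing")
  progression_date <- progression_date %||% as.Date(NA)
  death_date <- death_date %||% as.Date(NA)
  next_line_start <- next_line_start %||% as.Date(NA)
  censor_date <- min_date(last_followup_date, death_date, next_line_start)
  if (!is.na(progression_date)) {
    t <- as.numeric(progression_date - line_start)
    return(list(time_months = days_to_months(max(t, 0)), event = TRUE,
                event_date = progression_date))
  }
  if (death_is_event && !is.na(death_date) && death_date <= censor_date) {
    t <- as.numeric(death_date - line_start)
    return(list(time_months = days_to_months(max(t, 0)), event = TRUE,
                event_date = death_date))
  }
  if (is.na(censor_date)) stopf("no censoring date available")
  t <- as.numeric(censor_date - line_start)
  list(time_months = days_to_months(max(t, 0)), event = FALSE,
       event_date = censor_date)
}

#' Reclassify clinically failing patients as non-responders
#'
#' Patients who changed therapy or died within six months (182 days) of
#' their follow-up examination did not benefit from treatment regardless of
#' the imaging category: their responder flag is forced to `FALSE`. The
#' category itself is unchanged; the override is recorded in `detail`.
#'
#' @param results Per-line classification data.frame (as produced by
#'   [classify_cohort()]'s `summary`), with `patient_id`, `responder`,
#'   `assessment_date`, `detail`.
#' @param cohort The `patient_cohort` carrying therapy-change and death dates.
#' @param within_days Window after the follow-up examination (default 182,
#'   i.e. six months fixed for determinism).
#' @return `results` with overridden `responder` flags.
#' @export
reclassify_nonresponders <- function(results, cohort, within_days = 182) {
  for (i in seq_len(nrow(results))) {
    if (is.na(results$responder[i]) || !results$responder[i]) next
    ad <- results$assessment_date[i]
    if (is.na(ad)) next
    pc <- cohort[[results$patient_id[i]]]
    events <- c(pc$therapy_change_dates, pc$death_date)
    events <- events[!is.na(events)]
    delta <- as.numeric(events - ad)
    hit <- delta >= 0 & delta <= within_days
    if (any(hit)) {
      results$responder[i] <- FALSE
      what <- c(rep("therapy change", length(pc$therapy_change_dates)),
                "death")[!is.na(c(pc$therapy_change_dates, pc$death_date))][hit]
      results$detail[i] <- paste0(
        results$detail[i],
        sprintf(" | reclassified non-responder: %s %d d after follow-up exam",
                what[1], as.integer(min(delta[hit]))))
    }
  }
  results
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time Non-negative survival times (months).
#' @param event Logical event indicators (`FALSE` = censored).
#' @return List of class `km_curve`: `curve` (data.frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`) and `median` (smallest time
#'   with survival at or below 0.5; `NA` if the curve never reaches 0.5).
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) stopf("empty survival input")
  stopifnot(length(time) == length(event), all(time >= 0))
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & !event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  curve <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                      n_censor = n_censor, survival = surv)
  med_idx <- which(surv <= 0.5)
  median <- if (length(med_idx) == 0) NA_real_ else ut[min(med_idx)]
  structure(list(curve = curve, median = median, n = length(time),
                 n_events = sum(event)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, events = %d, median = %s months\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

# Log-rank O/E/V table over pooled event times (group a vs pooled).
logrank_oe <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- c(rep(TRUE, length(time_a)), rep(FALSE, length(time_b)))
  ut <- sort(unique(time[event]))
  O_a <- E_a <- V <- 0
  O_b <- E_b <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk); n_a <- sum(at_risk & grp_a)
    d <- sum(time == t & event); d_a <- sum(time == t & event & grp_a)
    O_a <- O_a + d_a
    O_b <- O_b + (d - d_a)
    E_a <- E_a + d * n_a / n
    E_b <- E_b + d * (n - n_a) / n
    if (n > 1)
      V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  list(O_a = O_a, E_a = E_a, O_b = O_b, E_b = E_b, V = V)
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank test with the conditional
#' hypergeometric variance for tied event times. `method = "permutation"`
#' replaces the chi-square approximation by the permutation distribution of
#' the statistic under random reassignment of group labels: exhaustive when
#' the number of label assignments is at most `exhaustive_limit`, otherwise
#' `n_perm` Monte-Carlo draws.
#'
#' @param time_a,event_a,time_b,event_b Survival times (months) and event
#'   indicators for the two groups.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm Monte-Carlo permutation count (default 10000).
#' @param exhaustive_limit Enumerate all label assignments when
#'   `choose(n, n_a)` is at most this (default 20000).
#' @return List: `chisq`, `p`, `method`, O/E bookkeeping (`O_a`, `E_a`,
#'   `O_b`, `E_b`, `V`), and for permutation mode `n_perm_used` and
#'   `exhaustive`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b,
                         method = c("asymptotic", "permutation"),
                         n_perm = 10000, exhaustive_limit = 20000) {
  method <- match.arg(method)
  if (length(time_a) == 0 || length(time_b) == 0)
    stopf("both groups must be non-empty")
  oe <- logrank_oe(time_a, event_a, time_b, event_b)
  if (oe$V <= 0) {
    warning("degenerate log-rank instance (no informative event times); p = 1")
    return(list(chisq = 0, p = 1, method = method, O_a = oe$O_a,
                E_a = oe$E_a, O_b = oe$O_b, E_b = oe$E_b, V = oe$V))
  }
  chisq <- (oe$O_a - oe$E_a)^2 / oe$V
  if (method == "asymptotic") {
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    return(list(chisq = chisq, p = p, method = method, O_a = oe$O_a,
                E_a = oe$E_a, O_b = oe$O_b, E_b = oe$E_b, V = oe$V))
  }
  time <- c(time_a, time_b); event <- c(event_a, event_b)
  n <- length(time); n_a <- length(time_a)
  stat_for <- function(idx_a) {
    sel <- logical(n); sel[idx_a] <- TRUE
    o <- logrank_oe(time[sel], event[sel], time[!sel], event[!sel])
    if (o$V <= 0) 0 else (o$O_a - o$E_a)^2 / o$V
  }
  exhaustive <- choose(n, n_a) <= exhaustive_limit
  stats_perm <- if (exhaustive) {
    combos <- utils::combn(n, n_a)
    apply(combos, 2, stat_for)
  } else {
    vapply(seq_len(n_perm), function(k) stat_for(sample.int(n, n_a)),
           numeric(1))
  }
  p <- mean(stats_perm >= chisq - 1e-9)
  list(chisq = chisq, p = p, method = method, O_a = oe$O_a, E_a = oe$E_a,
       O_b = oe$O_b, E_b = oe$E_b, V = oe$V,
       n_perm_used = length(stats_perm), exhaustive = exhaustive)
}

#' Hazard ratio between two groups
#'
#' Default estimator is the Mantel-Haenszel ratio of observed-to-expected
#' event counts from the log-rank table, HR = (O_a/E_a)/(O_b/E_b), with a
#' 95% CI from the normal approximation on the log scale using
#' Var(log HR) ~ 1/E_a + 1/E_b. This matches the logrank hazard ratio
#' printed by common survival-analysis software. `method = "cox"` fits a
#' Cox partial-likelihood model instead (requires the survival package).
#'
#' @inheritParams logrank_test
#' @param method `"mantel-haenszel"` (default) or `"cox"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `hr`, `ci_lower`, `ci_upper`, `method`, `unbounded`
#'   (`TRUE` when a group has zero events and the CI is unbounded).
#' @export
hazard_ratio <- function(time_a, event_a, time_b, event_b,
                         method = c("mantel-haenszel", "cox"),
                         conf_level = 0.95) {
  method <- match.arg(method)
  if (method == "cox") {
    if (!requireNamespace("survival", quietly = TRUE))
      stopf("method = 'cox' requires the survival package")
    grp <- c(rep(1, length(time_a)), rep(0, length(time_b)))
    fit <- survival::coxph(
      survival::Surv(c(time_a, time_b), c(event_a, event_b)) ~ grp)
    ci <- exp(stats::confint(fit, level = conf_level))
    return(list(hr = unname(exp(stats::coef(fit))), ci_lower = ci[1],
                ci_upper = ci[2], method = method, unbounded = FALSE))
  }
  oe <- logrank_oe(time_a, event_a, time_b, event_b)
  if (oe$O_a == 0 || oe$O_b == 0) {
    hr <- if (oe$E_a > 0 && oe$E_b > 0 && oe$O_b > 0)
      (oe$O_a / oe$E_a) / (oe$O_b / oe$E_b) else NA_real_
    warning("zero events in a group: hazard ratio CI unbounded")
    return(list(hr = hr, ci_lower = 0, ci_upper = Inf, method = method,
                unbounded = TRUE))
  }
  hr <- (oe$O_a / oe$E_a) / (oe$O_b / oe$E_b)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / oe$E_a + 1 / oe$E_b)
  list(hr = hr, ci_lower = exp(log(hr) - z * se),
       ci_upper = exp(log(hr) + z * se), method = method, unbounded = FALSE)
}

#' Cross-tabulate two classification streams
#'
#' Builds the concordance table between two criteria over jointly evaluable
#' patients (NE under either criterion drops the patient) and derives
#' per-category agreement percents: for each category of the row criterion,
#' the percent of those patients receiving the same category under the
#' column criterion, rounded half away from zero to integers.
#'
#' @param results_a,results_b Per-line classification data.frames with
#'   `patient_id` and `category` (typically one row per patient).
#' @param label_a,label_b Names for the two criteria (defaults taken from a
#'   `criterion` column when present).
#' @return List of class `concordance_table`: `counts` (contingency table),
#'   `agreement` (data.frame: category, n_row, n_agree, percent),
#'   `overall_percent`, `n`.
#' @export
concordance <- function(results_a, results_b, label_a = NULL, label_b = NULL) {
  label_a <- label_a %||% (if ("criterion" %in% names(results_a))
    results_a$criterion[1] else "A")
  label_b <- label_b %||% (if ("criterion" %in% names(results_b))
    results_b$criterion[1] else "B")
  m <- merge(results_a[, c("patient_id", "category")],
             results_b[, c("patient_id", "category")],
             by = "patient_id", suffixes = c("_a", "_b"))
  m <- m[m$category_a != "NE" & m$category_b != "NE", , drop = FALSE]
  if (nrow(m) == 0) {
    warning("no jointly evaluable patients shared between the two streams")
    return(structure(list(counts = table(character(), character()),
                          agreement = data.frame(), overall_percent = NA_real_,
                          n = 0, labels = c(label_a, label_b)),
                     class = "concordance_table"))
  }
  lev <- c("CR", "PR", "SD", "PD")
  counts <- table(factor(m$category_a, levels = lev),
                  factor(m$category_b, levels = lev), dnn = c(label_a, label_b))
  agree_rows <- lapply(lev, function(cat) {
    n_row <- sum(m$category_a == cat)
    if (n_row == 0) return(NULL)
    n_agree <- sum(m$category_a == cat & m$category_b == cat)
    data.frame(category = cat, n_row = n_row, n_agree = n_agree,
               percent = round_half_up(100 * n_agree / n_row),
               stringsAsFactors = FALSE)
  })
  agreement <- do.call(rbind, agree_rows)
  structure(list(counts = counts, agreement = agreement,
                 overall_percent = round_half_up(
                   100 * sum(m$category_a == m$category_b) / nrow(m)),
                 n = nrow(m), labels = c(label_a, label_b)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("<concordance_table> %s vs %s, n = %d jointly evaluable\n",
              x$labels[1], x$labels[2], x$n))
  print(x$counts)
  if (nrow(x$agreement) > 0) {
    cat("per-category agreement (%):\n")
    print(x$agreement, row.names = FALSE)
  }
  invisible(x)
}
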