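# Hand-built fixtures used across test files.

fixture_lesions <- function(pid, dates, diam, iodine = NULL, aorta = NULL,
                            lesion_id = "L1") {
  data.frame(lesion_id = lesion_id, timepoint_date = as.Date(dates),
             longest_diameter_mm = diam,
             iodine_mg_per_ml = iodine %||% rep(NA_real_, length(dates)),
             aortic_iodine_mg_per_ml = aorta %||% rep(NA_real_, length(dates)),
             location = "pelvis", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One patient: single lesion measured twice with size + iodine, CA125 series
# responding, one treatment line.
fixture_course <- function(pid = "PT01", setting = "relapse") {
  patient_course(
    patient_id = pid,
    lesions = fixture_lesions(pid, c("2021-01-01", "2021-04-01"),
                              diam = c(29.8, 35.0),
                              iodine = c(1.4, 1.1), aorta = c(7.0, 7.0)),
    ca125 = data.frame(
      sample_date = as.Date(c("2021-01-01", "2021-02-01", "2021-03-15")),
      value_u_per_ml = c(200, 95, 92)),
    treatment_lines = data.frame(line_index = 1L,
                                 start_date = as.Date("2021-01-01"),
                                 end_date = as.Date(NA)),
    uln_u_per_ml = 35, setting = setting,
    last_followup_date = as.Date("2021-10-01"))
}

fixture_cohort <- function(n = 3) {
  patient_cohort(lapply(seq_len(n), function(i)
    fixture_course(sprintf("PT%02d", i))))
}

# A patient with two scans but iodine values at only `k` of them.
fixture_iodine_patient <- function(pid, k) {
  dates <- as.Date("2021-01-01") + 90 * (seq_len(max(k, 2)) - 1)
  patient_course(
    patient_id = pid,
    lesions = fixture_lesions(pid, dates, diam = rep(20, length(dates)),
                              iodine = c(rep(1.5, k),
                                         rep(NA_real_, length(dates) - k)),
                              aorta = c(rep(7, k),
                                        rep(NA_real_, length(dates) - k))),
    treatment_lines = data.frame(line_index = 1L, start_date = dates[1],
                                 end_date = as.Date(NA)),
    last_followup_date = max(dates))
}
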