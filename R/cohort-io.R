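# CSV-bundle and JSON interchange for patient cohorts.
#
# CSV bundle layout (UTF-8, header row): patients.csv, lesions.csv,
# ca125.csv, treatment_lines.csv in one directory. All dates ISO-8601.
# Diameters are stored in mm; lesions.csv may carry an optional
# `diameter_unit` column ("mm" or "cm") and cm values are converted on
# ingestion (RECIST practice is mm, radiology reports often print cm).

PATIENT_COLS <- c("patient_id", "uln_u_per_ml", "setting", "death_date",
                  "last_followup_date", "therapy_change_dates")

read_table_checked <- function(file, required, label) {
  if (!file.exists(file)) stopf("cohort bundle is missing %s", basename(file))
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stopf("schema error in %s: missing required column(s) %s",
          basename(file), paste(missing, collapse = ", "))
  df
}

parse_date_col <- function(df, col, file) {
  raw <- df[[col]]
  parsed <- parse_iso_date(raw)
  bad <- which(!is.na(raw) & nzchar(raw) & is.na(parsed))
  if (length(bad) > 0)
    stopf("unparseable date in %s column %s at data row(s) %s (value '%s')",
          file, col, paste(bad, collapse = ", "), raw[bad[1]])
  parsed
}

num_or_na <- function(x) {
  x[!nzchar(trimws(x))] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read a patient cohort from disk
#'
#' @param path Directory containing the four-table CSV bundle
#'   (`patients.csv`, `lesions.csv`, `ca125.csv`, `treatment_lines.csv`),
#'   or a JSON file produced by [write_cohort()].
#' @param format `"csv_bundle"` or `"json"`.
#' @return A `patient_cohort`. Rows violating domain invariants abort with
#'   row-level diagnostics; duplicate (patient, lesion, timepoint) rows are an
#'   integrity error.
#' @export
read_cohort <- function(path, format = c("csv_bundle", "json")) {
  format <- match.arg(format)
  if (format == "json") return(read_cohort_json(path))
  if (!dir.exists(path)) stopf("cohort bundle directory not found: %s", path)

  pts <- read_table_checked(file.path(path, "patients.csv"), PATIENT_COLS,
                            "patients.csv")
  les <- read_table_checked(file.path(path, "lesions.csv"),
                            c("patient_id", LESION_COLS), "lesions.csv")
  ca  <- read_table_checked(file.path(path, "ca125.csv"),
                            c("patient_id", CA125_COLS), "ca125.csv")
  tl  <- read_table_checked(file.path(path, "treatment_lines.csv"),
                            c("patient_id", LINE_COLS), "treatment_lines.csv")

  les$timepoint_date <- parse_date_col(les, "timepoint_date", "lesions.csv")
  ca$sample_date <- parse_date_col(ca, "sample_date", "ca125.csv")
  tl$start_date <- parse_date_col(tl, "start_date", "treatment_lines.csv")
  tl$end_date <- parse_date_col(tl, "end_date", "treatment_lines.csv")
  pts$death_date <- parse_date_col(pts, "death_date", "patients.csv")
  pts$last_followup_date <- parse_date_col(pts, "last_followup_date",
                                           "patients.csv")

  dup <- duplicated(les[, c("patient_id", "lesion_id", "timepoint_date")])
  if (any(dup))
    stopf("integrity error: duplicate (patient_id, lesion_id, timepoint_date) at lesions.csv data row(s) %s",
          paste(which(dup), collapse = ", "))

  les$longest_diameter_mm <- num_or_na(les$longest_diameter_mm)
  les$iodine_mg_per_ml <- num_or_na(les$iodine_mg_per_ml)
  les$aortic_iodine_mg_per_ml <- num_or_na(les$aortic_iodine_mg_per_ml)
  if ("diameter_unit" %in% names(les)) {
    cm <- !is.na(les$diameter_unit) & les$diameter_unit == "cm"
    les$longest_diameter_mm[cm] <- les$longest_diameter_mm[cm] * 10
  }
  bad <- which(is.na(les$longest_diameter_mm) | les$longest_diameter_mm < 0)
  if (length(bad) > 0)
    stopf("invariant violation in lesions.csv data row(s) %s: longest_diameter_mm must be a number >= 0",
          paste(bad, collapse = ", "))
  ca$value_u_per_ml <- num_or_na(ca$value_u_per_ml)
  tl$line_index <- as.integer(num_or_na(tl$line_index))
  pts$uln_u_per_ml <- num_or_na(pts$uln_u_per_ml)
  pts$uln_u_per_ml[is.na(pts$uln_u_per_ml)] <- 35

  courses <- lapply(seq_len(nrow(pts)), function(i) {
    pid <- pts$patient_id[i]
    tcd <- pts$therapy_change_dates[i]
    tcd <- if (is.na(tcd) || !nzchar(tcd)) character() else
      strsplit(tcd, ";", fixed = TRUE)[[1]]
    patient_course(
      patient_id = pid,
      lesions = les[les$patient_id == pid, LESION_COLS, drop = FALSE],
      ca125 = ca[ca$patient_id == pid, CA125_COLS, drop = FALSE],
      treatment_lines = tl[tl$patient_id == pid, LINE_COLS, drop = FALSE],
      uln_u_per_ml = pts$uln_u_per_ml[i],
      setting = pts$setting[i],
      death_date = pts$death_date[i],
      therapy_change_dates = tcd,
      last_followup_date = pts$last_followup_date[i])
  })
  patient_cohort(courses)
}

fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
fmt_num <- function(x) ifelse(is.na(x), "", vapply(x, format, character(1),
                                                   digits = 15))

#' Write a patient cohort to disk
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x))` reproduces `x`
#' field for field. Optional fields absent in the cohort are emitted as empty
#' cells and survive the round trip as `NA`.
#'
#' @param cohort A `patient_cohort`.
#' @param path Output directory (csv_bundle) or file (json).
#' @param format `"csv_bundle"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv_bundle", "json")) {
  format <- match.arg(format)
  if (format == "json") return(write_cohort_json(cohort, path))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stopf("cannot create output directory %s", path)

  pts <- rbind_rows(lapply(cohort, function(pc) data.frame(
    patient_id = pc$patient_id,
    uln_u_per_ml = fmt_num(pc$uln_u_per_ml),
    setting = pc$setting,
    death_date = fmt_date(pc$death_date),
    last_followup_date = fmt_date(pc$last_followup_date),
    therapy_change_dates = paste(fmt_date(pc$therapy_change_dates),
                                 collapse = ";"),
    stringsAsFactors = FALSE)))
  if (is.null(pts)) pts <- empty_chr_df(PATIENT_COLS)
  bind_tab <- function(field, cols) {
    rows <- lapply(cohort, function(pc) {
      df <- pc[[field]]
      if (nrow(df) == 0) return(NULL)
      cbind(data.frame(patient_id = pc$patient_id, stringsAsFactors = FALSE), df)
    })
    out <- rbind_rows(rows)
    if (is.null(out)) out <- empty_chr_df(c("patient_id", cols))
    for (cc in names(out))
      out[[cc]] <- if (inherits(out[[cc]], "Date")) fmt_date(out[[cc]])
        else if (is.numeric(out[[cc]])) fmt_num(out[[cc]]) else out[[cc]]
    out
  }
  utils::write.csv(pts, file.path(path, "patients.csv"), row.names = FALSE,
                   quote = TRUE)
  utils::write.csv(bind_tab("lesions", LESION_COLS),
                   file.path(path, "lesions.csv"), row.names = FALSE)
  utils::write.csv(bind_tab("ca125", CA125_COLS),
                   file.path(path, "ca125.csv"), row.names = FALSE)
  utils::write.csv(bind_tab("treatment_lines", LINE_COLS),
                   file.path(path, "treatment_lines.csv"), row.names = FALSE)
  invisible(path)
}

course_to_list <- function(pc) {
  list(patient_id = pc$patient_id,
       uln_u_per_ml = pc$uln_u_per_ml,
       setting = pc$setting,
       death_date = fmt_date(pc$death_date),
       last_followup_date = fmt_date(pc$last_followup_date),
       therapy_change_dates = as.list(fmt_date(pc$therapy_change_dates)),
       lesions = within(pc$lesions, timepoint_date <- fmt_date(timepoint_date)),
       ca125 = within(pc$ca125, sample_date <- fmt_date(sample_date)),
       treatment_lines = within(pc$treatment_lines, {
         start_date <- fmt_date(start_date); end_date <- fmt_date(end_date)
       }))
}

write_cohort_json <- function(cohort, path) {
  doc <- list(format = "patient_cohort", version = 1L,
              patients = lapply(unname(cohort), course_to_list))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

read_cohort_json <- function(path) {
  if (!file.exists(path)) stopf("cohort JSON not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  pats <- doc$patients
  blank_na <- function(x) { x[!is.na(x) & !nzchar(x)] <- NA_character_; x }
  courses <- lapply(seq_len(length(pats$patient_id)), function(i) {
    les <- pats$lesions[[i]]
    if (is.null(les) || length(les) == 0 || nrow(as.data.frame(les)) == 0)
      les <- empty_lesions()
    ca <- pats$ca125[[i]]
    if (is.null(ca) || length(ca) == 0 || nrow(as.data.frame(ca)) == 0)
      ca <- empty_ca125()
    tl <- pats$treatment_lines[[i]]
    if (is.null(tl) || length(tl) == 0 || nrow(as.data.frame(tl)) == 0)
      tl <- empty_lines()
    tcd <- unlist(pats$therapy_change_dates[[i]])
    patient_course(
      patient_id = pats$patient_id[i],
      lesions = as.data.frame(les),
      ca125 = as.data.frame(ca),
      treatment_lines = as.data.frame(tl),
      uln_u_per_ml = pats$uln_u_per_ml[i],
      setting = pats$setting[i],
      death_date = blank_na(pats$death_date[i]),
      therapy_change_dates = if (is.null(tcd)) character() else tcd,
      last_followup_date = blank_na(pats$last_followup_date[i]))
  })
  patient_cohort(courses)
}
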