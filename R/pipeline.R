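# End-to-end orchestration: simulate -> classify x3 -> non-responder
# reclassification -> survival / concordance / threshold sweep -> report
# files, with a reproducibility manifest (config snapshot, seed, row
# counts, output digests). Logging goes to stderr; stdout stays
# machine-readable.

log_msg <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

write_df <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort (or reads one), classifies every patient under the
#' RECIST, DECT and GCIG CA125 criteria, applies the six-month
#' therapy-change/death non-responder override, derives per-criterion
#' progression-free survival with Kaplan-Meier, log-rank and hazard-ratio
#' summaries, cross-tabulates the criteria, sweeps the DECT threshold over
#' 10/15/20% against the CA125/clinical reference, and writes a waterfall
#' table of percent change with response duration. All outputs are CSV/JSON
#' under `out_dir`; a `manifest.json` records the config, seed, row counts
#' and file digests so a re-run can be verified byte for byte.
#'
#' @param config A `simulation_config`, a path to a JSON config file, or
#'   `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed (overrides the config seed).
#' @param cohort_path Optional path to an existing cohort CSV bundle; when
#'   given, simulation is skipped.
#' @param criteria Criteria to run (default all three).
#' @param subset Survival subset, `"relapse"` (default) or `"all"`.
#' @param thresholds Sweep thresholds (default 10, 15, 20).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = NULL,
                         cohort_path = NULL,
                         criteria = c("recist", "dect", "ca125"),
                         subset = c("relapse", "all"),
                         thresholds = c(10, 15, 20)) {
  subset <- match.arg(subset)
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (is.character(config)) config <- read_sim_config_json(config)
  config <- config %||% simulation_config()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  counts <- list()

  if (is.null(cohort_path)) {
    log_msg("INFO", "stage simulate: n = %d patients", config$n_patients)
    cohort <- simulate_cohort(config, seed = seed)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    files <- c(files, file.path(out_dir, "cohort",
                                c("patients.csv", "lesions.csv", "ca125.csv",
                                  "treatment_lines.csv")))
    truth <- attr(cohort, "truth")
    files <- c(files, write_df(truth, file.path(out_dir, "truth.csv")))
  } else {
    log_msg("INFO", "stage read: %s", cohort_path)
    cohort <- read_cohort(cohort_path)
    truth <- NULL
  }
  counts$patients <- length(cohort)

  elig <- eligibility_filter(cohort)
  counts$evaluable <- length(elig$evaluable)
  counts$excluded <- nrow(elig$report)
  if (nrow(elig$report) > 0)
    files <- c(files, write_df(elig$report, file.path(out_dir, "exclusions.csv")))
  cohort <- elig$evaluable
  log_msg("INFO", "stage eligibility: %d evaluable, %d excluded",
          counts$evaluable, counts$excluded)

  log_msg("INFO", "stage classify: %s", paste(criteria, collapse = ", "))
  cls <- classify_cohort(cohort, criteria = criteria)
  summary <- reclassify_nonresponders(cls$summary, cohort)
  if (!is.null(cls$timepoints))
    files <- c(files, write_df(cls$timepoints,
                               file.path(out_dir, "classifications_timepoints.csv")))
  files <- c(files, write_df(summary, file.path(out_dir, "classifications.csv")))
  counts$classification_rows <- nrow(summary)

  # waterfall analog: percent change + response duration per patient/criterion
  wf <- lapply(toupper(criteria), function(cr) {
    rec <- survival_records(summary, cohort, cr, subset = subset)
    sm <- summary[summary$criterion == cr, ,drop = FALSE]
    m <- merge(sm[, c("patient_id", "category", "percent_change", "responder")],
               rec[, c("patient_id", "time_months", "event")],
               by = "patient_id")
    if (nrow(m) > 0) cbind(criterion = cr, m) else NULL
  })
  wf <- do.call(rbind, wf)
  if (!is.null(wf))
    files <- c(files, write_df(wf, file.path(out_dir, "waterfall.csv")))

  for (cr in toupper(criteria)) {
    rec <- survival_records(summary, cohort, cr, subset = subset)
    if (nrow(rec) == 0 || length(unique(rec$responder)) < 2) {
      log_msg("WARN", "stage survival: %s skipped (a group is empty)", cr)
      next
    }
    cmp <- compare_survival(rec)
    files <- c(files, write_df(rec, file.path(out_dir,
                                              sprintf("survival_records_%s.csv", tolower(cr)))))
    km <- rbind(cbind(group = "responder", cmp$km_responder$curve),
                cbind(group = "nonresponder", cmp$km_nonresponder$curve))
    files <- c(files, write_df(km, file.path(out_dir,
                                             sprintf("km_%s.csv", tolower(cr)))))
    sfile <- file.path(out_dir, sprintf("survival_summary_%s.json", tolower(cr)))
    jsonlite::write_json(
      list(criterion = cr, subset = subset,
           n_responder = cmp$n_responder, n_nonresponder = cmp$n_nonresponder,
           median_responder = cmp$median_responder,
           median_nonresponder = cmp$median_nonresponder,
           chisq = cmp$chisq, p = cmp$p, hr = cmp$hr,
           ci_lower = cmp$ci_lower, ci_upper = cmp$ci_upper),
      sfile, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    files <- c(files, sfile)
    log_msg("INFO", "stage survival %s: median %s vs %s months, p = %.4f",
            cr, format(cmp$median_responder), format(cmp$median_nonresponder),
            cmp$p)
  }

  pairs <- utils::combn(toupper(criteria), 2, simplify = FALSE)
  for (pr in pairs) {
    a <- summary[summary$criterion == pr[1], , drop = FALSE]
    b <- summary[summary$criterion == pr[2], , drop = FALSE]
    ct <- concordance(a, b)
    if (ct$n == 0) next
    cfile <- file.path(out_dir, sprintf("concordance_%s_%s.csv",
                                        tolower(pr[1]), tolower(pr[2])))
    files <- c(files, write_df(as.data.frame(ct$counts,
                                             responseName = "n"), cfile))
  }

  if ("dect" %in% criteria) {
    dect <- summary[summary$criterion == "DECT", , drop = FALSE]
    ref <- reference_nonresponder_labels(summary, cohort)
    m <- merge(dect[, c("patient_id", "percent_change")], ref,
               by = "patient_id")
    if (sum(!is.na(m$nonresponder)) > 0) {
      sw <- threshold_sweep(m$percent_change, m$nonresponder, thresholds)
      files <- c(files, write_df(sw$table, file.path(out_dir, "sweep.csv")))
      log_msg("INFO", "stage sweep: selected threshold %g%%", sw$selected)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dectresponse")),
    seed = seed %||% config$seed,
    subset = subset,
    config = config[setdiff(names(config), "seed")],
    counts = counts,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)
  log_msg("INFO", "pipeline complete: %d files in %s", length(files) + 1,
          out_dir)
  invisible(manifest)
}

# Reference non-responder labels for the threshold sweep: GCIG CA125
# non-response where evaluable, otherwise the clinical outcome (therapy
# change or death within 6 months of the last scan).
reference_nonresponder_labels <- function(summary, cohort) {
  ca <- summary[summary$criterion == "CA125", c("patient_id", "responder")]
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  out <- data.frame(patient_id = ids, nonresponder = NA, row.names = NULL)
  m <- match(out$patient_id, ca$patient_id)
  out$nonresponder <- !ca$responder[m]
  for (i in which(is.na(out$nonresponder))) {
    pc <- cohort[[out$patient_id[i]]]
    tps <- imaging_timepoints(pc)
    if (length(tps) == 0) next
    events <- c(pc$therapy_change_dates, pc$death_date)
    events <- events[!is.na(events)]
    delta <- as.numeric(events - max(tps))
    out$nonresponder[i] <- any(delta >= 0 & delta <= 182)
  }
  out
}

read_sim_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  for (nm in c("size_effect_percent", "iodine_effect_percent",
               "hazard_months"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(simulation_config, raw)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `classify`, `sweep`, `survival`, `concordance`,
#' `run`. Global flags: `--seed`, `--config`, `--out`, `--json`,
#' `--criterion`, `--threshold`, `--thresholds`, `--subset`, `--cohort`,
#' `--a`, `--b`. Exit codes: 0 success, 2 validation error, 3 stage
#' failure. Logs go to stderr; with `--json`, a machine-readable result is
#' printed on stdout.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit code, invisibly.
#' @export
response_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dectresponse <simulate|classify|sweep|survival|concordance|run> [flags]",
    "  --out DIR        output directory (required)",
    "  --seed INT       RNG seed",
    "  --config PATH    simulation config JSON",
    "  --cohort DIR     existing cohort CSV bundle (skips simulation)",
    "  --criterion C    recist|dect|ca125 (classify/survival)",
    "  --threshold T    DECT boundary percent (default 15)",
    "  --thresholds L   comma list for sweep (default 10,15,20)",
    "  --subset S       relapse|all (default relapse)",
    "  --a C --b C      criteria for concordance",
    "  --json           machine-readable stdout", sep = "\n")
  flags <- list(); cmd <- NULL; i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      if (!is.null(cmd)) { message("unexpected argument: ", a); return(invisible(2)) }
      cmd <- a; i <- i + 1; next
    }
    key <- substring(a, 3)
    if (key %in% c("json")) { flags[[key]] <- TRUE; i <- i + 1; next }
    if (i == length(args)) { message("missing value for --", key); return(invisible(2)) }
    flags[[key]] <- args[i + 1]; i <- i + 2
  }
  if (is.null(cmd) || !cmd %in% c("simulate", "classify", "sweep", "survival",
                                  "concordance", "run")) {
    message(usage); return(invisible(2))
  }
  if (is.null(flags$out)) { message("--out is required\n", usage); return(invisible(2)) }
  seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else NULL
  res <- tryCatch({
    config <- if (!is.null(flags$config)) read_sim_config_json(flags$config)
      else simulation_config()
    out <- flags$out
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    get_cohort <- function() {
      if (!is.null(flags$cohort)) read_cohort(flags$cohort)
      else simulate_cohort(config, seed = seed)
    }
    payload <- switch(cmd,
      simulate = {
        cohort <- simulate_cohort(config, seed = seed)
        write_cohort(cohort, file.path(out, "cohort"))
        write_df(attr(cohort, "truth"), file.path(out, "truth.csv"))
        list(n_patients = length(cohort))
      },
      classify = {
        crit <- tolower(flags$criterion %||% "dect")
        cohort <- eligibility_filter(get_cohort())$evaluable
        cls <- classify_cohort(cohort, criteria = crit,
                               threshold_percent = as.numeric(flags$threshold %||% 15))
        write_df(cls$summary, file.path(out, sprintf("classifications_%s.csv", crit)))
        list(criterion = crit, n = nrow(cls$summary))
      },
      sweep = {
        ths <- as.numeric(strsplit(flags$thresholds %||% "10,15,20", ",")[[1]])
        cohort <- eligibility_filter(get_cohort())$evaluable
        cls <- classify_cohort(cohort)
        summary <- reclassify_nonresponders(cls$summary, cohort)
        dect <- summary[summary$criterion == "DECT", , drop = FALSE]
        ref <- reference_nonresponder_labels(summary, cohort)
        m <- merge(dect[, c("patient_id", "percent_change")], ref, "patient_id")
        sw <- threshold_sweep(m$percent_change, m$nonresponder, ths)
        write_df(sw$table, file.path(out, "sweep.csv"))
        list(selected = sw$selected)
      },
      survival = {
        crit <- toupper(flags$criterion %||% "dect")
        cohort <- eligibility_filter(get_cohort())$evaluable
        cls <- classify_cohort(cohort)
        summary <- reclassify_nonresponders(cls$summary, cohort)
        rec <- survival_records(summary, cohort, crit,
                                subset = flags$subset %||% "relapse")
        cmp <- compare_survival(rec)
        write_df(rec, file.path(out, sprintf("survival_records_%s.csv",
                                             tolower(crit))))
        list(criterion = crit, median_responder = cmp$median_responder,
             median_nonresponder = cmp$median_nonresponder, p = cmp$p,
             hr = cmp$hr, ci = c(cmp$ci_lower, cmp$ci_upper))
      },
      concordance = {
        cohort <- eligibility_filter(get_cohort())$evaluable
        cls <- classify_cohort(cohort)
        a <- toupper(flags$a %||% "DECT"); b <- toupper(flags$b %||% "CA125")
        ct <- concordance(cls$summary[cls$summary$criterion == a, ],
                          cls$summary[cls$summary$criterion == b, ])
        write_df(as.data.frame(ct$counts, responseName = "n"),
                 file.path(out, sprintf("concordance_%s_%s.csv",
                                        tolower(a), tolower(b))))
        list(a = a, b = b, n = ct$n, overall_percent = ct$overall_percent)
      },
      run = {
        man <- run_pipeline(config, out, seed = seed,
                            cohort_path = flags$cohort,
                            subset = flags$subset %||% "relapse")
        list(manifest = file.path(out, "manifest.json"),
             patients = man$counts$patients)
      })
    if (isTRUE(flags$json))
      cat(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA), "\n")
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("invalid|schema|unparseable|unknown config", conditionMessage(e)))
      2L else 3L
  })
  invisible(res)
}
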