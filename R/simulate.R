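# Synthetic relapsed ovarian cancer cohorts: a latent responder status
# drives correlated lesion-size shrinkage, iodine-concentration decline,
# CA125 decline and longer exponential time-to-progression, with
# multiplicative log-normal measurement noise and administrative censoring.
# Defaults echo the printed structure of the motivating cohort (40 patients,
# 1-5 target lesions each, ~69% with an iodine decrease, 80% relapsed)
# without claiming to match any unpublished distribution.

#' Build a simulation configuration
#'
#' All quantities are positive scales unless noted. Treatment effects are
#' mean percent changes per treatment line (a step from baseline, visible at
#' every follow-up scan); measurement noise is multiplicative log-normal
#' with coefficient of variation `measurement_cv` on sizes, iodine and
#' CA125. Aortic iodine is drawn per scan, so aortic normalization is
#' consequential. PFS is exponential per latent group with scale (mean) in
#' months.
#'
#' @param n_patients Number of patients (default 40).
#' @param responder_fraction Latent responder probability (default 0.69).
#' @param relapse_fraction Fraction treated for relapsed disease (default 0.8).
#' @param n_lesions_range Integer range of target lesions per patient
#'   (default 1 to 5).
#' @param baseline_diameter_mm Log-normal parameters (`meanlog`, `sdlog`) for
#'   baseline longest diameters.
#' @param baseline_iodine_mg_per_ml Log-normal parameters for baseline lesion
#'   iodine concentration.
#' @param aortic_iodine_mg_per_ml Normal parameters (`mean`, `sd`), truncated
#'   positive (> 1 mg/mL), drawn per scan.
#' @param size_effect_percent Named vector `c(responder=, nonresponder=)`:
#'   mean percent SLD change per line.
#' @param iodine_effect_percent Same for normalized iodine concentration.
#' @param ca125 List: `pre_meanlog`, `pre_sdlog` (pre-treatment value),
#'   `responder_rate_per_month`, `nonresponder_rate_per_month` (log-linear
#'   drift rates).
#' @param hazard_months Named vector: exponential PFS scale (mean months)
#'   per group.
#' @param censoring_months Administrative censoring horizon (default 12).
#' @param measurement_cv Coefficient of variation of measurement noise
#'   (default 0.10).
#' @param uln_u_per_ml CA125 ULN (default 35).
#' @param scan_months Follow-up scan schedule in months after treatment
#'   start (default 3 and 6; baseline scan is at start).
#' @param ca125_interval_days CA125 sampling interval (default 30).
#' @param death_probability Probability of death after observed progression
#'   (default 0.2), with an exponential delay of mean 3 months.
#' @param start_date First possible treatment start (ISO date).
#' @param seed Default RNG seed carried in the config (may be overridden).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 40,
                              responder_fraction = 0.69,
                              relapse_fraction = 0.8,
                              n_lesions_range = c(1, 5),
                              baseline_diameter_mm = list(meanlog = log(30), sdlog = 0.5),
                              baseline_iodine_mg_per_ml = list(meanlog = log(1.8), sdlog = 0.4),
                              aortic_iodine_mg_per_ml = list(mean = 7, sd = 1.2),
                              size_effect_percent = c(responder = -30, nonresponder = 25),
                              iodine_effect_percent = c(responder = -30, nonresponder = 30),
                              ca125 = list(pre_meanlog = log(300), pre_sdlog = 0.6,
                                           responder_rate_per_month = -0.55,
                                           nonresponder_rate_per_month = 0.35),
                              hazard_months = c(responder = 10, nonresponder = 5),
                              censoring_months = 12,
                              measurement_cv = 0.10,
                              uln_u_per_ml = 35,
                              scan_months = c(3, 6),
                              ca125_interval_days = 30,
                              death_probability = 0.2,
                              start_date = "2020-01-01",
                              seed = NULL) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  problems <- validate_simulation_config(cfg)
  if (length(problems) > 0)
    stopf("invalid simulation config: %s", paste(problems, collapse = "; "))
  cfg
}

validate_simulation_config <- function(cfg) {
  p <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) p <<- c(p, msg)
  chk(is.numeric(cfg$n_patients) && cfg$n_patients >= 1, "n_patients >= 1")
  chk(cfg$responder_fraction >= 0 && cfg$responder_fraction <= 1,
      "responder_fraction in [0, 1]")
  chk(cfg$relapse_fraction >= 0 && cfg$relapse_fraction <= 1,
      "relapse_fraction in [0, 1]")
  chk(length(cfg$n_lesions_range) == 2 && cfg$n_lesions_range[1] >= 1 &&
        cfg$n_lesions_range[2] >= cfg$n_lesions_range[1],
      "n_lesions_range must be an increasing positive integer pair")
  chk(cfg$measurement_cv >= 0, "measurement_cv >= 0")
  chk(all(cfg$hazard_months > 0), "hazard_months scales > 0")
  chk(cfg$censoring_months > 0, "censoring_months > 0")
  chk(cfg$uln_u_per_ml > 0, "uln_u_per_ml > 0")
  chk(all(cfg$scan_months > 0), "scan_months > 0")
  chk(cfg$ca125_interval_days > 0, "ca125_interval_days > 0")
  chk(cfg$death_probability >= 0 && cfg$death_probability <= 1,
      "death_probability in [0, 1]")
  chk(all(c("responder", "nonresponder") %in% names(cfg$size_effect_percent)),
      "size_effect_percent needs responder/nonresponder entries")
  chk(all(c("responder", "nonresponder") %in% names(cfg$iodine_effect_percent)),
      "iodine_effect_percent needs responder/nonresponder entries")
  p
}

# Truncated-positive normal draw (> lower).
rnorm_trunc <- function(n, mean, sd, lower = 1) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# Mean-one multiplicative log-normal noise with coefficient of variation cv.
rnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Simulate a patient cohort
#'
#' Deterministic given `seed` and config. Each patient receives a latent
#' responder status; responders get negative mean drift in SLD, normalized
#' iodine and CA125 and a longer exponential PFS, non-responders the
#' reverse. Imaging happens at baseline and at `scan_months` (jittered a few
#' days); CA125 is sampled at `ca125_interval_days`. Scans and samples stop
#' at death or the censoring horizon. Ground truth (latent status, true
#' progression time) is attached as `attr(cohort, "truth")`.
#'
#' @param config A `simulation_config`.
#' @param seed RNG seed; overrides `config$seed`.
#' @return A `patient_cohort` with a `truth` attribute (data.frame:
#'   `patient_id`, `responder`, `setting`, `true_pfs_months`, `event`,
#'   `observed_time_months`).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = NULL) {
  problems <- validate_simulation_config(config)
  if (length(problems) > 0)
    stopf("invalid simulation config: %s", paste(problems, collapse = "; "))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  start0 <- parse_iso_date(cfg$start_date)
  month_days <- 30.4375
  n <- cfg$n_patients
  courses <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%04d", i)
    responder <- stats::runif(1) < cfg$responder_fraction
    grp <- if (responder) "responder" else "nonresponder"
    setting <- if (stats::runif(1) < cfg$relapse_fraction) "relapse"
      else "first_line"
    start <- start0 + round(stats::runif(1, 0, 90))
    n_les <- sample(seq(cfg$n_lesions_range[1], cfg$n_lesions_range[2]), 1)

    # latent per-lesion baselines: diameter (mm) and aorta-normalized iodine
    base_diam <- stats::rlnorm(n_les, cfg$baseline_diameter_mm$meanlog,
                               cfg$baseline_diameter_mm$sdlog)
    base_ratio <- stats::rlnorm(n_les, cfg$baseline_iodine_mg_per_ml$meanlog,
                                cfg$baseline_iodine_mg_per_ml$sdlog) /
      cfg$aortic_iodine_mg_per_ml$mean

    # latent outcome
    t_prog <- stats::rexp(1, rate = 1 / cfg$hazard_months[[grp]])
    event <- t_prog <= cfg$censoring_months
    first_scan_m <- min(cfg$scan_months)
    death_m <- NA_real_
    if (event && stats::runif(1) < cfg$death_probability)
      death_m <- max(t_prog + stats::rexp(1, 1 / 3), first_scan_m + 0.5)
    change_m <- if (event) t_prog + 14 / month_days else NA_real_
    horizon_m <- min(cfg$censoring_months, death_m, na.rm = TRUE)

    # imaging: baseline at start, follow-ups per schedule until the horizon
    jitter_d <- round(stats::runif(length(cfg$scan_months), -10, 10))
    scan_m <- c(0, pmax(cfg$scan_months + jitter_d / month_days, 0.5))
    scan_m <- scan_m[scan_m <= horizon_m | scan_m == 0]
    if (length(scan_m) == 1 && !is.na(death_m))  # keep an end-of-line scan
      scan_m <- c(0, min(first_scan_m, horizon_m - 0.1))
    scan_dates <- start + round(scan_m * month_days)
    size_eff <- 1 + cfg$size_effect_percent[[grp]] / 100
    iod_eff <- 1 + cfg$iodine_effect_percent[[grp]] / 100
    les_rows <- list()
    for (s in seq_along(scan_dates)) {
      treated <- scan_m[s] > 0
      aorta <- rnorm_trunc(1, cfg$aortic_iodine_mg_per_ml$mean,
                           cfg$aortic_iodine_mg_per_ml$sd)
      diam <- base_diam * (if (treated) size_eff else 1) *
        rnoise(n_les, cfg$measurement_cv)
      ratio <- base_ratio * (if (treated) iod_eff else 1) *
        rnoise(n_les, cfg$measurement_cv)
      les_rows[[s]] <- data.frame(
        lesion_id = sprintf("%s-L%02d", pid, seq_len(n_les)),
        timepoint_date = scan_dates[s],
        longest_diameter_mm = round(diam, 1),
        iodine_mg_per_ml = round(ratio * aorta, 3),
        aortic_iodine_mg_per_ml = round(aorta, 3),
        location = "peritoneum", stringsAsFactors = FALSE)
    }

    # CA125: pre-treatment sample at start, then log-linear drift
    pre <- stats::rlnorm(1, cfg$ca125$pre_meanlog, cfg$ca125$pre_sdlog)
    rate <- if (responder) cfg$ca125$responder_rate_per_month
      else cfg$ca125$nonresponder_rate_per_month
    samp_m <- seq(0, horizon_m, by = cfg$ca125_interval_days / month_days)
    ca_vals <- pmax(pre * exp(rate * samp_m) *
                      rnoise(length(samp_m), cfg$measurement_cv), 1)
    ca <- data.frame(sample_date = start + round(samp_m * month_days),
                     value_u_per_ml = round(ca_vals, 1))
    ca <- ca[!duplicated(ca$sample_date), , drop = FALSE]

    death_date <- if (is.na(death_m)) NULL else start + round(death_m * month_days)
    last_fu <- start + round(horizon_m * month_days)
    changes <- if (!is.na(change_m) && change_m <= horizon_m + 6)
      start + round(change_m * month_days) else as.Date(character())

    courses[[i]] <- patient_course(
      patient_id = pid,
      lesions = do.call(rbind, les_rows),
      ca125 = ca,
      treatment_lines = data.frame(line_index = 1L, start_date = start,
                                   end_date = as.Date(NA)),
      uln_u_per_ml = cfg$uln_u_per_ml,
      setting = setting,
      death_date = death_date,
      therapy_change_dates = changes,
      last_followup_date = last_fu)
    truth[[i]] <- data.frame(
      patient_id = pid, responder = responder, setting = setting,
      true_pfs_months = t_prog, event = event,
      observed_time_months = min(t_prog, horizon_m),
      stringsAsFactors = FALSE)
  }
  cohort <- patient_cohort(courses)
  attr(cohort, "truth") <- rbind_rows(truth)
  class(cohort) <- c("patient_cohort")
  cohort
}

#' Survival records from simulation ground truth
#'
#' Bypasses the classification engines: time is the latent progression time
#' (censored at the horizon actually observed) and the group is the latent
#' responder status. Used for hazard-ratio parameter-recovery checks.
#'
#' @param cohort A simulated cohort carrying a `truth` attribute.
#' @return data.frame shaped like [survival_records()] output.
#' @export
truth_survival_records <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) stopf("cohort carries no simulation ground truth")
  data.frame(patient_id = tr$patient_id, criterion = "TRUTH",
             time_months = tr$observed_time_months, event = tr$event,
             responder = tr$responder, stringsAsFactors = FALSE)
}

#' Recovery of the latent responder status by the criteria engines
#'
#' Simulates (or takes) a cohort, runs all three engines and tabulates how
#' well each criterion's responder call recovers the latent status over
#' patients the criterion could evaluate.
#'
#' @param config A `simulation_config` (ignored when `cohort` is given).
#' @param threshold_percent DECT boundary (default 15).
#' @param seed RNG seed.
#' @param cohort Optional pre-simulated cohort with a `truth` attribute.
#' @return List per criterion: `confusion` (2x2 table predicted vs latent)
#'   and `accuracy`; plus `n_classified` per criterion.
#' @export
classification_recovery <- function(config = simulation_config(),
                                    threshold_percent = 15, seed = NULL,
                                    cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config, seed = seed)
  truth <- attr(cohort, "truth")
  cls <- classify_cohort(cohort, threshold_percent = threshold_percent)
  sm <- merge(cls$summary, truth[, c("patient_id", "responder")],
              by = "patient_id", suffixes = c("_pred", "_true"))
  out <- list()
  for (cr in unique(sm$criterion)) {
    s <- sm[sm$criterion == cr & !is.na(sm$responder_pred), , drop = FALSE]
    conf <- table(predicted = s$responder_pred, latent = s$responder_true)
    out[[cr]] <- list(confusion = conf,
                      accuracy = if (nrow(s) > 0)
                        mean(s$responder_pred == s$responder_true) else NA_real_,
                      n_classified = nrow(s))
  }
  out
}

#' Synthetic percent-change data with a known decision boundary
#'
#' A boundary-calibration fixture for [threshold_sweep()]: reference
#' non-responders' iodine percent changes are centred `separation` above the
#' responders', with the true decision boundary midway at
#' `true_threshold`. With the defaults, responders centre at 0% (stable
#' perfusion) and non-responders at +30%, so 15% is the generative boundary.
#'
#' @param n Number of patients (default 200).
#' @param true_threshold Generative boundary in percent (default 15).
#' @param separation Distance between group means in percent (default 30).
#' @param sd Within-group standard deviation (default 6).
#' @param nonresponder_fraction Fraction of reference non-responders
#'   (default 0.5).
#' @param seed RNG seed.
#' @return data.frame: `patient_id`, `percent_change`, `nonresponder`.
#' @export
simulate_sweep_data <- function(n = 200, true_threshold = 15,
                                separation = 30, sd = 6,
                                nonresponder_fraction = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nonresp <- stats::runif(n) < nonresponder_fraction
  mu <- ifelse(nonresp, true_threshold + separation / 2,
               true_threshold - separation / 2)
  data.frame(patient_id = sprintf("S%04d", seq_len(n)),
             percent_change = stats::rnorm(n, mu, sd),
             nonresponder = nonresp, stringsAsFactors = FALSE)
}
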