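# Independent brute-force oracles. These deliberately re-derive the rules
# by literal pair enumeration, independent of the engine code paths.

# GCIG CA125 response: a pair (s1, s2) after treatment start, both at or
# below half the pre-treatment value, s2 at least 28 days after s1, no
# sample above half between them. Returns earliest qualifying s1 date.
oracle_ca125_response <- function(dates, values, start, pre,
                                  confirm_days = 28) {
  post <- which(dates > start)
  half <- pre / 2
  hits <- as.Date(character())
  if (length(post) >= 2) {
    for (i in post) for (j in post) {
      if (dates[j] <= dates[i]) next
      if (values[i] > half || values[j] > half) next
      if (as.numeric(dates[j] - dates[i]) < confirm_days) next
      between <- post[dates[post] > dates[i] & dates[post] < dates[j]]
      if (any(values[between] > half)) next
      hits <- c(hits, dates[i])
    }
  }
  if (length(hits) == 0) list(responded = FALSE, response_date = as.Date(NA))
  else list(responded = TRUE, response_date = min(hits))
}

# GCIG CA125 progression: pair enumeration with the running nadir (minimum
# of the pre-treatment value and post-treatment samples up to s1); patients
# whose nadir normalized (<= ULN) progress at 2 x ULN, else at 2 x nadir,
# threshold frozen at s1; two samples at/above it at least 7 days apart.
oracle_ca125_progression <- function(dates, values, start, uln, pre,
                                     gap_days = 7) {
  post <- which(dates > start)
  hits <- as.Date(character())
  if (length(post) >= 2) {
    for (i in post) {
      upto <- post[dates[post] <= dates[i]]
      nadir <- min(c(pre, values[upto]))
      thr <- if (nadir <= uln) 2 * uln else 2 * nadir
      if (values[i] < thr) next
      for (j in post) {
        if (as.numeric(dates[j] - dates[i]) < gap_days) next
        if (values[j] >= thr) hits <- c(hits, dates[i])
      }
    }
  }
  if (length(hits) == 0) list(progressed = FALSE, progression_date = as.Date(NA))
  else list(progressed = TRUE, progression_date = min(hits))
}

# Random CA125 series for oracle equivalence, with boundary values (exactly
# half the pre-treatment value, exactly 2 x ULN) and boundary gaps (exactly
# 7 or 28 days) injected with non-trivial probability.
random_ca125_series <- function(uln = 35) {
  n <- sample(1:6, 1)
  start <- as.Date("2021-03-01")
  dates <- start + sort(sample(1:120, n))
  pre <- round(runif(1, 60, 500), 1)
  values <- round(runif(n, 10, 800), 1)
  snap <- runif(n) < 0.25
  values[snap] <- sample(c(pre / 2, 2 * uln, 2 * pre), sum(snap),
                         replace = TRUE)
  if (n >= 2 && runif(1) < 0.3)
    dates[n] <- dates[n - 1] + sample(c(7, 28), 1)
  list(dates = dates, values = values, start = start, pre = pre, uln = uln)
}

# Exhaustive permutation log-rank p-value using survival::survdiff as the
# independent statistic implementation.
oracle_perm_logrank <- function(time, event, n_a) {
  obs <- oracle_logrank_chisq(time[seq_len(n_a)], event[seq_len(n_a)],
                              time[-seq_len(n_a)], event[-seq_len(n_a)])
  combos <- utils::combn(length(time), n_a)
  stats <- apply(combos, 2, function(idx) {
    sel <- seq_along(time) %in% idx
    oracle_logrank_chisq(time[sel], event[sel], time[!sel], event[!sel])
  })
  list(chisq = obs, p = mean(stats >= obs - 1e-9))
}

oracle_logrank_chisq <- function(ta, ea, tb, eb) {
  grp <- c(rep(0, length(ta)), rep(1, length(tb)))
  sd <- survival::survdiff(survival::Surv(c(ta, tb), c(ea, eb)) ~ grp)
  unname(sd$chisq)
}
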