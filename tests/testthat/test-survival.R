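start <- as.Date("2021-01-01")

test_that("derive_pfs converts days to months and handles censoring", {
  # progression at day 152 -> 4.99 months, event
  p <- derive_pfs(start, progression_date = start + 152,
                  last_followup_date = start + 300)
  expect_equal(round_half_up(p$time_months, 2), 4.99)
  expect_true(p$event)
  # no progression, last follow-up day 300 -> 9.86 months, censored
  c1 <- derive_pfs(start, last_followup_date = start + 300)
  expect_equal(round_half_up(c1$time_months, 2), 9.86)
  expect_false(c1$event)
  # progression on the start date -> 0 months, event
  z <- derive_pfs(start, progression_date = start,
                  last_followup_date = start + 100)
  expect_equal(z$time_months, 0)
  expect_true(z$event)
  # death before last follow-up: event by default, censoring when disabled
  d1 <- derive_pfs(start, death_date = start + 120,
                   last_followup_date = start + 300)
  expect_true(d1$event)
  expect_equal(d1$time_months, days_to_months(120))
  d2 <- derive_pfs(start, death_date = start + 120,
                   last_followup_date = start + 300, death_is_event = FALSE)
  expect_false(d2$event)
  expect_equal(d2$time_months, days_to_months(120))
  # censoring never exceeds last follow-up minus line start; next line caps
  n1 <- derive_pfs(start, last_followup_date = start + 300,
                   next_line_start = start + 90)
  expect_equal(n1$time_months, days_to_months(90))
  expect_error(derive_pfs(as.Date(NA), last_followup_date = start + 10),
               "start date missing")
})

test_that("KM product-limit estimator and median", {
  # all events at 1..5: S = .8 .6 .4 .2 0, median = smallest t with S <= .5
  km <- km_curve(1:5, rep(TRUE, 5))
  expect_equal(km$curve$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)
  expect_equal(km_curve(4, TRUE)$median, 4)
  expect_true(is.na(km_curve(1:5, rep(FALSE, 5))$median))
  expect_error(km_curve(numeric(), logical()), "empty")
  # no censoring: KM equals the empirical survival function (property)
  set.seed(8)
  t <- round(rexp(40, 0.2), 2)
  km2 <- km_curve(t, rep(TRUE, 40))
  emp <- vapply(km2$curve$time, function(x) mean(t > x), numeric(1))
  expect_equal(km2$curve$survival, emp)
})

test_that("KM estimator matches survival::survfit under censoring", {
  set.seed(21)
  t <- round(rexp(60, 0.15), 2)
  ev <- runif(60) < 0.7
  km <- km_curve(t, ev)
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
  ours <- km$curve$survival[km$curve$n_event > 0]
  theirs <- sf$surv[sf$n.event > 0]
  expect_equal(ours, theirs)
})

test_that("log-rank: identical groups give statistic 0, p = 1", {
  t <- c(2, 4, 6, 8); e <- c(TRUE, TRUE, FALSE, TRUE)
  lr <- logrank_test(t, e, t, e)
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p, 1)
})

test_that("log-rank statistic matches survdiff on random instances", {
  set.seed(99)
  for (i in 1:25) {
    na <- sample(3:15, 1); nb <- sample(3:15, 1)
    ta <- round(rexp(na, 0.2), 1); tb <- round(rexp(nb, 0.35), 1)
    ea <- runif(na) < 0.8; eb <- runif(nb) < 0.8
    if (sum(ea) + sum(eb) < 2) next
    lr <- logrank_test(ta, ea, tb, eb)
    expect_equal(lr$chisq, oracle_logrank_chisq(ta, ea, tb, eb),
                 tolerance = 1e-10)
  }
})

test_that("log-rank is invariant under positive time rescaling", {
  set.seed(5)
  ta <- rexp(12, 0.2); tb <- rexp(10, 0.5)
  ea <- rep(TRUE, 12); eb <- c(rep(TRUE, 8), FALSE, FALSE)
  lr1 <- logrank_test(ta, ea, tb, eb)
  lr2 <- logrank_test(7.3 * ta, ea, 7.3 * tb, eb)
  expect_equal(lr2$chisq, lr1$chisq)
  expect_equal(lr2$p, lr1$p)
})

test_that("clearly separated groups give p < 0.001", {
  ta <- 20 + (1:20); tb <- 1:20  # one group strictly larger, no censoring
  lr <- logrank_test(ta, rep(TRUE, 20), tb, rep(TRUE, 20))
  expect_lt(lr$p, 0.001)
})

test_that("degenerate instances warn and return p = 1", {
  expect_warning(lr <- logrank_test(5, FALSE, 7, FALSE), "degenerate")
  expect_equal(lr$p, 1)
})

test_that("hazard ratio: identity, inversion, unbounded CI", {
  t <- c(2, 4, 6, 8, 10); e <- rep(TRUE, 5)
  expect_equal(hazard_ratio(t, e, t, e)$hr, 1)
  set.seed(3)
  ta <- rexp(30, 0.2); tb <- rexp(30, 0.5)
  h <- hazard_ratio(ta, rep(TRUE, 30), tb, rep(TRUE, 30))
  hswap <- hazard_ratio(tb, rep(TRUE, 30), ta, rep(TRUE, 30))
  expect_equal(hswap$hr, 1 / h$hr, tolerance = 1e-10)
  expect_warning(hz <- hazard_ratio(c(3, 5), c(FALSE, FALSE), c(1, 2),
                                    c(TRUE, TRUE)), "unbounded")
  expect_true(hz$unbounded)
  expect_equal(hz$ci_upper, Inf)
})

test_that("MH hazard ratio recovers a true HR of 0.5 (n = 500/500)", {
  set.seed(1234)
  ta <- rexp(500, 0.5); tb <- rexp(500, 1)
  h <- hazard_ratio(ta, rep(TRUE, 500), tb, rep(TRUE, 500))
  expect_gt(h$hr, 0.4)
  expect_lt(h$hr, 0.62)
  # Cox mode agrees to ~10%
  hc <- hazard_ratio(ta, rep(TRUE, 500), tb, rep(TRUE, 500), method = "cox")
  expect_equal(h$hr, hc$hr, tolerance = 0.1)
})

test_that("reclassify_nonresponders applies the 6-month clinical override", {
  mk_course <- function(pid, change = NULL, death = NULL) {
    patient_course(pid,
                   lesions = fixture_lesions(pid, c("2021-01-01", "2021-04-01"),
                                             diam = c(20, 20)),
                   treatment_lines = data.frame(line_index = 1L,
                                                start_date = start,
                                                end_date = as.Date(NA)),
                   death_date = death, therapy_change_dates = change %||% character(),
                   last_followup_date = as.Date("2022-06-01"))
  }
  res <- data.frame(patient_id = c("A", "B", "C"), criterion = "DECT",
                    category = c("SD", "PR", "SD"),
                    responder = c(TRUE, TRUE, TRUE),
                    assessment_date = as.Date("2021-04-01"),
                    detail = "x", stringsAsFactors = FALSE)
  co <- patient_cohort(list(
    mk_course("A", change = as.Date("2021-04-01") + 90),   # +90 d -> override
    mk_course("B", death = as.Date("2021-04-01") + 200),   # +200 d -> keep
    mk_course("C")))                                       # no events -> keep
  out <- reclassify_nonresponders(res, co)
  expect_equal(out$responder, c(FALSE, TRUE, TRUE))
  expect_match(out$detail[1], "reclassified non-responder")
  expect_equal(out$category, res$category)  # category never changes
  # boundary: event exactly 182 days after the exam still overrides
  co2 <- patient_cohort(list(mk_course("A", change = as.Date("2021-04-01") + 182),
                             mk_course("B"), mk_course("C")))
  expect_false(reclassify_nonresponders(res, co2)$responder[1])
})

test_that("concordance cross-tabulates jointly evaluable patients", {
  a <- data.frame(patient_id = sprintf("p%02d", 1:11), criterion = "DECT",
                  category = "PD", stringsAsFactors = FALSE)
  b <- data.frame(patient_id = sprintf("p%02d", 1:11), criterion = "CA125",
                  category = c(rep("PD", 9), "SD", "SD"),
                  stringsAsFactors = FALSE)
  ct <- concordance(a, b)
  expect_equal(ct$n, 11)
  expect_equal(ct$agreement$percent[ct$agreement$category == "PD"], 82)
  # identical streams: diagonal table, 100% agreement
  ct2 <- concordance(b, b)
  expect_equal(ct2$overall_percent, 100)
  expect_true(all(ct2$counts[row(ct2$counts) != col(ct2$counts)] == 0))
  # NE rows drop out of the joint set
  b2 <- b; b2$category[1] <- "NE"
  expect_equal(concordance(a, b2)$n, 10)
  # disjoint patient sets warn and return an empty table
  b3 <- b; b3$patient_id <- sprintf("q%02d", 1:11)
  expect_warning(ct3 <- concordance(a, b3), "no jointly evaluable")
  expect_equal(ct3$n, 0)
})

test_that("compare_survival produces the grouped summary", {
  set.seed(12)
  rec <- data.frame(
    patient_id = sprintf("r%02d", 1:30), criterion = "DECT",
    time_months = c(rexp(20, 1 / 8), rexp(10, 1 / 3)),
    event = rep(TRUE, 30),
    responder = c(rep(TRUE, 20), rep(FALSE, 10)), stringsAsFactors = FALSE)
  cmp <- compare_survival(rec)
  expect_equal(cmp$n_responder, 20)
  expect_equal(cmp$n_nonresponder, 10)
  expect_lt(cmp$hr, 1)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
})
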