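start <- as.Date("2021-01-01")

test_that("eligibility gate: pre-treatment value at least twice the ULN", {
  d <- start - 3
  expect_true(ca125_eligibility(d, 200, start, uln = 35)$evaluable)
  expect_false(ca125_eligibility(d, 60, start, uln = 35)$evaluable)
  expect_true(ca125_eligibility(d, 70, start, uln = 35)$evaluable)  # inclusive
  # latest sample within the window wins; none -> not evaluable with reason
  e <- ca125_eligibility(c(start - 10, start - 2), c(300, 80), start, 35)
  expect_equal(e$pretreatment_value, 80)
  miss <- ca125_eligibility(start - 60, 300, start, 35)
  expect_false(miss$evaluable)
  expect_match(miss$reason, "no CA125 sample")
})

test_that("response: 50% fall maintained >= 28 days, no intervening breach", {
  # 95 (day 21) and 92 (day 56): both <= 100, 35 d gap -> response at day 21
  r <- ca125_response(start + c(21, 56), c(95, 92), start, pretreatment = 200)
  expect_true(r$responded)
  expect_equal(r$response_date, start + 21)
  # single unconfirmed sample
  expect_false(ca125_response(start + 21, 90, start, 200)$responded)
  # intervening breach kills the day-21 window; day 60 lacks confirmation
  r2 <- ca125_response(start + c(21, 35, 60), c(95, 130, 90), start, 200)
  expect_false(r2$responded)
  # ... but a confirming sample after day 60 revives it
  r3 <- ca125_response(start + c(21, 35, 60, 95), c(95, 130, 90, 85), start, 200)
  expect_true(r3$responded)
  expect_equal(r3$response_date, start + 60)
  # boundary: gap of exactly 28 days and values exactly half
  r4 <- ca125_response(start + c(10, 38), c(100, 100), start, 200)
  expect_true(r4$responded)
})

test_that("progression: 2 x nadir (or 2 x ULN when normalized), week apart", {
  # never normalized: nadir 40 > ULN 35, threshold 80
  p <- ca125_progression(start + c(50, 100, 110), c(40, 85, 90), start,
                         uln = 35, pretreatment = 200)
  expect_true(p$progressed)
  expect_equal(p$progression_date, start + 100)
  # gap below 7 days fails
  p2 <- ca125_progression(start + c(50, 100, 103), c(40, 85, 90), start,
                          uln = 35, pretreatment = 200)
  expect_false(p2$progressed)
  # normalized patient progresses at 2 x ULN, not 2 x nadir
  p3 <- ca125_progression(start + c(30, 60, 90, 100), c(20, 25, 72, 75),
                          start, uln = 35, pretreatment = 200)
  expect_true(p3$progressed)
  expect_equal(p3$progression_date, start + 90)
  # ... so a rise clearing 2 x nadir but not 2 x ULN is NOT progression
  p3b <- ca125_progression(start + c(30, 60, 90, 100), c(20, 25, 50, 55),
                           start, uln = 35, pretreatment = 200)
  expect_false(p3b$progressed)
  # monotonically falling series never progresses
  p4 <- ca125_progression(start + c(30, 60, 90), c(150, 100, 80), start,
                          uln = 35, pretreatment = 300)
  expect_false(p4$progressed)
})

test_that("nadir is a running minimum: appending a sample never raises it", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    vals <- round(runif(n, 20, 400), 1)
    dates <- start + sort(sample(1:90, n))
    nad <- vapply(seq_len(n), function(k)
      ca125_progression(dates[1:k], vals[1:k], start, 35, 300)$nadir,
      numeric(1))
    expect_true(all(diff(nad) <= 0))
  }
})

test_that("decisions are invariant to date shifts and value/ULN rescaling", {
  set.seed(11)
  for (i in 1:30) {
    s <- random_ca125_series()
    shift <- sample(-500:500, 1)
    r0 <- ca125_response(s$dates, s$values, s$start, s$pre)
    r1 <- ca125_response(s$dates + shift, s$values, s$start + shift, s$pre)
    expect_equal(r1$responded, r0$responded)
    if (r0$responded) expect_equal(r1$response_date, r0$response_date + shift)
    k <- runif(1, 0.2, 5)
    p0 <- ca125_progression(s$dates, s$values, s$start, s$uln, s$pre)
    p1 <- ca125_progression(s$dates, k * s$values, s$start, k * s$uln,
                            k * s$pre)
    expect_equal(p1$progressed, p0$progressed)
    expect_equal(p1$progression_date, p0$progression_date)
  }
})

test_that("engine matches the brute-force oracle on random series", {
  set.seed(2024)
  for (i in 1:500) {
    s <- random_ca125_series()
    r_engine <- ca125_response(s$dates, s$values, s$start, s$pre)
    r_oracle <- oracle_ca125_response(s$dates, s$values, s$start, s$pre)
    expect_equal(r_engine$responded, r_oracle$responded,
                 label = sprintf("response case %d", i))
    if (r_oracle$responded)
      expect_equal(r_engine$response_date, r_oracle$response_date)
    p_engine <- ca125_progression(s$dates, s$values, s$start, s$uln, s$pre)
    p_oracle <- oracle_ca125_progression(s$dates, s$values, s$start, s$uln,
                                         s$pre)
    expect_equal(p_engine$progressed, p_oracle$progressed,
                 label = sprintf("progression case %d", i))
    if (p_oracle$progressed)
      expect_equal(p_engine$progression_date, p_oracle$progression_date)
  }
})

test_that("classify_gcig composes the rules over a course", {
  mk <- function(values, days, pre = 300) {
    patient_course("G1", ca125 = data.frame(
      sample_date = c(start, start + days),
      value_u_per_ml = c(pre, values)),
      treatment_lines = data.frame(line_index = 1L, start_date = start,
                                   end_date = as.Date(NA)),
      uln_u_per_ml = 35, last_followup_date = start + max(days))
  }
  # response day 30 confirmed day 70, then progression day 150/160
  pc <- mk(c(120, 110, 700, 720), c(30, 70, 150, 160))
  out <- classify_gcig(pc)
  expect_equal(out$category, "PR")
  expect_true(out$responder)
  expect_equal(out$progression_date, start + 150)  # retained for PFS
  # progression before response -> PD
  pd <- classify_gcig(mk(c(700, 720, 120), c(30, 40, 90)))
  expect_equal(pd$category, "PD")
  expect_false(pd$responder)
  # neither fires over 6 months -> SD
  sd <- classify_gcig(mk(c(250, 240, 230, 260), c(30, 60, 120, 180)))
  expect_equal(sd$category, "SD")
  # eligibility gate: pre-treatment below 2 x ULN -> NE
  ne <- classify_gcig(mk(c(40, 35), c(30, 60), pre = 60))
  expect_equal(ne$category, "NE")
  expect_true(is.na(ne$responder))
  expect_match(ne$detail, "2 x ULN")
})
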