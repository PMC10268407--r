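test_that("iodine is normalized to the aorta, with a flagged raw fallback", {
  expect_equal(normalize_iodine(1.4, 7.0), 0.2)
  expect_equal(normalize_iodine(0, 5.0), 0)
  expect_error(normalize_iodine(1.4, 0), "aortic")
  expect_error(normalize_iodine(1.4, NA), "fallback_raw")
  out <- normalize_iodine(c(1.4, 1.2), c(7.0, NA), fallback_raw = TRUE)
  expect_equal(unname(out), c(0.2, 1.2), ignore_attr = TRUE)
  expect_equal(attr(out, "unnormalized"), c(FALSE, TRUE))
})

test_that("aggregation mirrors SLD summation, with a mean mode", {
  expect_equal(aggregate_iodine(1.4), 1.4)
  expect_equal(aggregate_iodine(c(0.2, 0.3)), 0.5)
  expect_equal(aggregate_iodine(c(0.2, 0.3), mode = "mean"), 0.25)
  expect_error(aggregate_iodine(numeric()), "no iodine")
  expect_error(aggregate_iodine(c(0.2, NA)), "missing iodine")
})

test_that("classification: +/-theta inclusive boundaries, any-decrease flag", {
  pr <- classify_dect(1.4, 1.1)         # -21.43%
  expect_equal(pr$category, "PR")
  expect_true(pr$responder)
  expect_equal(round_half_up(pr$percent_change, 1), -21.4)
  pr2 <- classify_dect(1.1, 0.9)        # -18.18%
  expect_equal(pr2$category, "PR")
  expect_equal(classify_dect(100, 115)$category, "PD")   # exactly +15%
  expect_equal(classify_dect(100, 85)$category, "PR")    # exactly -15%
  sd <- classify_dect(100, 100)
  expect_equal(sd$category, "SD")
  expect_true(sd$responder)
  expect_false(sd$any_decrease)
  expect_true(classify_dect(100, 99)$any_decrease)
  expect_true(classify_dect(100, 114.9)$responder)  # below +15%: still responder
  expect_error(classify_dect(0, 1), "baseline")
  expect_error(classify_dect(1, 1, threshold_percent = 0), "threshold")
})

test_that("boundary partition: exactly one category fires per delta", {
  for (theta in c(10, 15, 20)) {
    deltas <- c(seq(-60, 60, by = 2.5), -theta, theta, -theta - 1e-6,
                theta - 1e-6)
    # baseline 100 makes percent_change(100, 100 + d) exactly d
    cats <- vapply(deltas, function(d)
      classify_dect(100, 100 + d, theta)$category, character(1))
    expect_true(all(cats %in% c("PR", "SD", "PD")))
    expect_equal(cats[deltas <= -theta], rep("PR", sum(deltas <= -theta)))
    expect_equal(cats[deltas >= theta], rep("PD", sum(deltas >= theta)))
    expect_equal(cats[abs(deltas) < theta], rep("SD", sum(abs(deltas) < theta)))
  }
})

test_that("classification is invariant under per-scan global iodine rescaling", {
  # multiplying every lesion AND the aorta at one timepoint by a constant
  # (contrast-dose variation) leaves the normalized classification unchanged
  dates <- as.Date(c("2021-01-01", "2021-04-01"))
  mk <- function(k1, k2) {
    les <- rbind(
      fixture_lesions("PT", dates, diam = c(20, 20),
                      iodine = c(1.4 * k1, 1.1 * k2),
                      aorta = c(7 * k1, 7 * k2), lesion_id = "L1"),
      fixture_lesions("PT", dates, diam = c(15, 15),
                      iodine = c(0.9 * k1, 0.8 * k2),
                      aorta = c(7 * k1, 7 * k2), lesion_id = "L2"))
    patient_course("PT", lesions = les,
                   treatment_lines = data.frame(line_index = 1L,
                                                start_date = dates[1],
                                                end_date = as.Date(NA)),
                   last_followup_date = dates[2])
  }
  base <- classify_imaging_course(mk(1, 1), criterion = "dect")
  for (kk in list(c(2, 0.5), c(0.3, 3), c(5, 5))) {
    out <- classify_imaging_course(mk(kk[1], kk[2]), criterion = "dect")
    expect_equal(out$summary$category, base$summary$category)
    expect_equal(out$summary$percent_change, base$summary$percent_change)
  }
  # raw mode is NOT invariant (this is why normalization matters)
  raw <- classify_imaging_course(mk(2, 0.5), criterion = "dect",
                                 normalized = FALSE)
  expect_false(isTRUE(all.equal(raw$summary$percent_change,
                                base$summary$percent_change)))
})

test_that("threshold sweep: agreement table, selection and tie-breaks", {
  # constructed labels: true boundary between 10 and 20
  pc <- c(-30, -20, -5, 0, 5, 12, 18, 25, 40, 30)
  ref <- pc >= 15
  sw <- threshold_sweep(pc, ref)
  expect_equal(sw$selected, 15)
  expect_equal(sw$table$threshold, c(10, 15, 20))
  expect_equal(sw$table$balanced_accuracy[2], 1)
  # all patients identical delta: every threshold ties, largest returned
  tie <- threshold_sweep(rep(5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(tie$selected, 20)
  # single-threshold sweep returns it
  expect_equal(threshold_sweep(pc, ref, thresholds = 10)$selected, 10)
  expect_error(threshold_sweep(numeric(), logical()), "no reference")
})

test_that("PD and PR call counts are non-increasing in the threshold", {
  set.seed(31)
  for (i in 1:20) {
    pc <- rnorm(100, 0, 25)
    ref <- pc + rnorm(100, 0, 10) > 15
    tab <- threshold_sweep(pc, ref, thresholds = c(5, 10, 15, 20, 30))$table
    expect_true(all(diff(tab$n_pd_calls) <= 0))
    expect_true(all(diff(tab$n_pr_calls) <= 0))
  }
})

test_that("sweep on data with a generative 15% boundary selects 15", {
  sw_data <- simulate_sweep_data(n = 200, true_threshold = 15, seed = 77)
  sw <- threshold_sweep(sw_data$percent_change, sw_data$nonresponder)
  expect_equal(sw$selected, 15)
})
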