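simple_ranges <- tibble::tibble(test_id = "T1", lower_limit = 5,
                                upper_limit = 10)

mk_meas <- function(values, dates = seq_along(values)) {
  tibble::tibble(test_id = "T1", value = values,
                 date = as.Date("2020-01-01") + dates)
}

test_that("direction predicates use strict inequalities at the limits", {
  def_up <- list(test_id = "T1", direction = "above_upper")
  def_lo <- list(test_id = "T1", direction = "below_lower")
  def_out <- list(test_id = "T1", direction = "outside_range")
  m <- mk_meas(c(8, 11))
  start <- as.Date("2020-01-01")
  expect_true(classify_patient_signal(m, def_up, simple_ranges, start))
  expect_false(classify_patient_signal(m, def_lo, simple_ranges, start))
  # boundary: 4.9 is outside, 5 and 10 are normal
  expect_true(classify_patient_signal(mk_meas(4.9), def_out, simple_ranges))
  expect_false(classify_patient_signal(mk_meas(5), def_out, simple_ranges))
  expect_false(classify_patient_signal(mk_meas(10), def_out, simple_ranges))
  expect_false(classify_patient_signal(mk_meas(10), def_up, simple_ranges))
  expect_error(
    classify_patient_signal(mk_meas(7), list(test_id = "T1",
                                             direction = "sideways"),
                            simple_ranges),
    "direction"
  )
  expect_error(
    classify_patient_signal(tibble::tibble(test_id = "T9", value = 1,
                                           date = start),
                            list(test_id = "T9", direction = "above_upper"),
                            tibble::tibble(test_id = character(),
                                           lower_limit = numeric(),
                                           upper_limit = numeric())),
    "reference range"
  )
})

test_that("outside_range is exactly the union of the one-sided directions", {
  # exhaustive boundary enumeration around the limits
  values <- c(4.9, 4.999, 5, 5.001, 7.5, 9.999, 10, 10.001, 11)
  lower <- 5; upper <- 10
  above <- values > upper
  below <- values < lower
  outside <- vapply(values, function(v) {
    classify_patient_signal(mk_meas(v),
                            list(test_id = "T1",
                                 direction = "outside_range"),
                            simple_ranges)
  }, logical(1))
  expect_identical(outside, above | below)
  one_sided <- vapply(seq_along(values), function(i) {
    classify_patient_signal(mk_meas(values[i]),
                            list(test_id = "T1", direction = "above_upper"),
                            simple_ranges) ||
      classify_patient_signal(mk_meas(values[i]),
                              list(test_id = "T1",
                                   direction = "below_lower"),
                              simple_ranges)
  }, logical(1))
  expect_identical(outside, one_sided)
})

test_that("enlarging the window never turns a classification false", {
  start <- as.Date("2020-01-01")
  m <- mk_meas(c(7, 12, 7), dates = c(10, 200, 300))
  def <- list(test_id = "T1", direction = "above_upper")
  prev <- FALSE
  for (w in c(50, 150, 250, 400)) {
    now <- classify_patient_signal(m, def, simple_ranges, start,
                                   window_days = w)
    expect_true(now >= prev)
    prev <- now
  }
  expect_true(prev)
})

test_that("a balanced four-patient design gives the unit table", {
  ehr <- list(
    exposures = tibble::tibble(
      patient_id = c("p1", "p2", "p3", "p4"),
      disease_code = "RA",
      drug_code = c("dx", "dx", "dy", "dy"),
      start_date = as.Date("2020-01-01")
    ),
    measurements = tibble::tibble(
      patient_id = c("p1", "p2", "p3", "p4"),
      test_id = "T1",
      value = c(12, 7, 12, 7),
      date = as.Date("2020-02-01")
    ),
    reference_ranges = simple_ranges
  )
  catalog <- tibble::tibble(signal_id = "S1", test_id = "T1",
                            direction = "above_upper")
  res <- screen_lab(ehr, catalog)
  expect_equal(nrow(res), 2)
  row <- res[res$drug == "dx", ]
  expect_equal(unlist(row[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(row$rr, 1)
  expect_false(row$significant)
})

test_that("embedded lab signals are recovered and tables match a per-patient recount", {
  catalog <- default_lab_catalog()
  truth <- ground_truth(lab_signals = tibble::tibble(
    drug = c("tocilizumab", "adalimumab"),
    signal_id = c("SIG039", "SIG002"),
    excursion_prob = 0.8
  ))
  cfg <- ehr_config(n_patients = c(RA = 600L),
                    background_abnormal_prob = 0.01,
                    tests_per_patient = 20L)
  ehr <- generate_ehr_lab(cfg, truth, seed = 81)
  res <- screen_lab(ehr, catalog$catalog)
  for (i in seq_len(nrow(truth$lab_signals))) {
    row <- res[res$drug == truth$lab_signals$drug[i] &
                 res$signal_id == truth$lab_signals$signal_id[i], ]
    expect_true(row$significant)
  }
  # patient partition: every pair's cells sum to the patient count
  expect_true(all(res$a + res$b + res$c + res$d ==
                    nrow(ehr$exposures)))
  # independent per-patient recount for a handful of pairs
  m <- dplyr::left_join(ehr$measurements, ehr$reference_ranges,
                        by = "test_id")
  set.seed(82)
  for (j in sample.int(nrow(res), 5)) {
    def <- catalog$catalog[catalog$catalog$signal_id == res$signal_id[j], ]
    hits <- vapply(ehr$exposures$patient_id, function(p) {
      classify_patient_signal(
        ehr$measurements[ehr$measurements$patient_id == p, ],
        def, ehr$reference_ranges,
        exposure_start = ehr$exposures$start_date[
          ehr$exposures$patient_id == p],
        window_days = 365L
      )
    }, logical(1))
    exposed <- ehr$exposures$drug_code == res$drug[j]
    expect_equal(res$a[j], sum(exposed & hits))
    expect_equal(res$c[j], sum(!exposed & hits))
  }
})

test_that("null lab data keeps the flag rate near the nominal level", {
  catalog <- default_lab_catalog()
  rates <- vapply(1:3, function(s) {
    ehr <- generate_ehr_lab(
      ehr_config(n_patients = c(RA = 500L),
                 background_abnormal_prob = 0.05,
                 tests_per_patient = 15L),
      seed = 90 + s
    )
    res <- screen_lab(ehr, catalog$catalog)
    mean(res$significant)
  }, numeric(1))
  n_pairs <- 3 * nrow(default_lab_catalog()$catalog) *
    length(unique(default_drug_table()$generic))
  expect_lt(mean(rates), 0.05 + 3 * sqrt(0.05 * 0.95 / n_pairs))
})
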