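small_registry_config <- function(...) {
  registry_config(
    n_patients = c(RA = 400L),
    drug_table = default_drug_table()[default_drug_table()$disease == "RA", ],
    term_table = default_term_table(10, 4),
    ...
  )
}

test_that("registry generation is deterministic and honours degenerate fractions", {
  cfg <- small_registry_config(withdrawal_fraction = 0)
  r1 <- generate_registry(cfg, seed = 11)
  r2 <- generate_registry(cfg, seed = 11)
  expect_identical(r1, r2)
  expect_false(any(r1$patients$withdrawal_flag))
  r3 <- generate_registry(cfg, seed = 12)
  expect_false(identical(r1$adr_reports, r3$adr_reports))
})

test_that("follow-ups exist only for non-withdrawn patients and reports attach to events", {
  cfg <- small_registry_config(withdrawal_fraction = 0.3)
  reg <- generate_registry(cfg, seed = 2)
  withdrawn <- reg$patients$patient_id[reg$patients$withdrawal_flag]
  fu <- reg$events[reg$events$phase == "follow_up", ]
  expect_length(intersect(fu$patient_id, withdrawn), 0)
  expect_true(all(reg$adr_reports$event_id %in% reg$events$event_id))
  expect_true(all(table(reg$patients$patient_id) == 1))
})

test_that("embedded pairs referencing unknown vocabulary fail loudly", {
  cfg <- small_registry_config()
  bad_drug <- ground_truth(registry_signals = tibble::tibble(
    disease = "RA", drug = "notadrug", term = "Headache", rr = 3
  ))
  expect_error(generate_registry(cfg, bad_drug, seed = 1), "notadrug")
  bad_term <- ground_truth(registry_signals = tibble::tibble(
    disease = "RA", drug = "etanercept", term = "Notaterm", rr = 3
  ))
  expect_error(generate_registry(cfg, bad_term, seed = 1), "Notaterm")
})

test_that("null generator keeps every pair at the baseline rate", {
  # rho = 1 everywhere: empirical related/indeterminate reporting rate of
  # each term stays within 3 binomial sigma of baseline at ~20,000 cases
  cfg <- registry_config(
    n_patients = c(RA = 5000L), n_followups = 4L,
    withdrawal_fraction = 0, baseline_prob = 0.02,
    status_probs = c(continued = 1, switched = 0, discontinued = 0,
                     other = 0),
    drug_table = default_drug_table()[default_drug_table()$disease == "RA", ],
    term_table = default_term_table(8, 2)
  )
  reg <- generate_registry(cfg, seed = 5)
  fu <- reg$events[reg$events$phase == "follow_up", ]
  n <- nrow(fu)
  expect_gte(n, 20000)
  rep_ri <- reg$adr_reports[
    reg$adr_reports$relatedness %in% c("related", "indeterminate"), ]
  per_term <- table(factor(rep_ri$raw_term,
                           levels = cfg$term_table$raw_term))
  p0 <- cfg$baseline_prob
  tol <- 3 * sqrt(p0 * (1 - p0) / n)
  expect_true(all(abs(per_term / n - p0) < tol))
})

test_that("srs generator handles empty input and is deterministic", {
  cfg <- srs_config(n_reports = 0L)
  empty <- generate_srs(cfg, seed = 1)
  expect_equal(nrow(empty), 0)
  cfg2 <- srs_config(n_reports = 2000L)
  s1 <- generate_srs(cfg2, seed = 3)
  s2 <- generate_srs(cfg2, seed = 3)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(grepl("^S\\d{7}$", s1$report_id)))
})

test_that("null srs matches an exact-independence permutation reference", {
  # over >= 10,000 (drug, event) pairs from rho = 1 universes, the fraction
  # of tables with ad > bc is about one half; small-count tables make the
  # statistic discretely skewed, so the reference value is computed from the
  # same universe with event sets randomly permuted across reports, which
  # enforces exact independence with identical margins
  drugs <- setNames(rep(1 / 30, 30), paste0("d", 1:30))
  events <- setNames(rep(1 / 50, 50), paste0("e", 1:50))
  frac_det_pos <- function(srs) {
    tab <- build_case_noncase(srs, list(brand_map = default_drug_table()))
    det <- tab$a * tab$d - tab$b * tab$c
    c(pos = sum(det > 0), tot = sum(det != 0))
  }
  permute_events <- function(srs) {
    d_by_r <- split(srs$drug_name, srs$report_id)
    e_by_r <- split(srs$event_term, srs$report_id)
    d_by_r <- lapply(d_by_r, unique)
    e_by_r <- lapply(e_by_r, unique)[sample(length(e_by_r))]
    nd <- lengths(d_by_r); ne <- lengths(e_by_r)
    tibble::tibble(
      report_id = rep(names(d_by_r), nd * ne),
      drug_name = unlist(Map(function(d, k) rep(d, each = k), d_by_r, ne)),
      event_term = unlist(Map(function(e, k) rep(e, times = k), e_by_r, nd))
    )
  }
  gen <- c(pos = 0, tot = 0); ref <- c(pos = 0, tot = 0)
  for (s in 1:8) {
    srs <- generate_srs(
      srs_config(n_reports = 4000L, drug_probs = drugs,
                 event_probs = events, brand_fraction = 0,
                 drug_table = default_drug_table()),
      seed = 100 + s
    )
    gen <- gen + frac_det_pos(srs)
    set.seed(900 + s)
    ref <- ref + frac_det_pos(permute_events(srs))
  }
  expect_gte(gen[["tot"]], 10000)
  p_gen <- gen[["pos"]] / gen[["tot"]]
  p_ref <- ref[["pos"]] / ref[["tot"]]
  # both are near one half ...
  expect_lt(abs(p_gen - 0.5), 0.05)
  expect_lt(abs(p_ref - 0.5), 0.05)
  # ... and agree with each other within Monte-Carlo error
  tol <- 3 * sqrt(0.25 / gen[["tot"]] + 0.25 / ref[["tot"]])
  expect_lt(abs(p_gen - p_ref), tol)
})

test_that("embedded srs signal lifts the conditional event rate", {
  truth <- ground_truth(srs_signals = tibble::tibble(
    drug = "etanercept", term = "Rash", rrr = 5
  ))
  hits <- vapply(1:3, function(s) {
    srs <- generate_srs(srs_config(n_reports = 20000L), truth, seed = s)
    tab <- build_case_noncase(srs, list(brand_map = default_drug_table()))
    row <- tab[tab$drug == "etanercept" & tab$event == "Rash", ]
    stats <- dispro_stats(row$a, row$b, row$c, row$d)
    stats$prr
  }, numeric(1))
  expect_true(all(hits > 1))
})

test_that("ehr generator respects degenerate settings and determinism", {
  cfg <- ehr_config(n_patients = c(RA = 120L),
                    background_abnormal_prob = 0,
                    tests_per_patient = 6L)
  ehr <- generate_ehr_lab(cfg, seed = 9)
  m <- dplyr::left_join(ehr$measurements, ehr$reference_ranges,
                        by = "test_id")
  expect_equal(sum(m$value > m$upper_limit | m$value < m$lower_limit), 0)
  expect_identical(generate_ehr_lab(cfg, seed = 9), ehr)
})

test_that("excursion probability one forces an abnormal value for every measured exposed patient", {
  catalog <- default_lab_catalog()
  truth <- ground_truth(lab_signals = tibble::tibble(
    drug = "tofacitinib", signal_id = "SIG001", excursion_prob = 1
  ))
  cfg <- ehr_config(n_patients = c(RA = 300L),
                    background_abnormal_prob = 0)
  ehr <- generate_ehr_lab(cfg, truth, seed = 4)
  test_id <- catalog$catalog$test_id[catalog$catalog$signal_id == "SIG001"]
  exposed <- ehr$exposures$patient_id[ehr$exposures$drug_code == "tofacitinib"]
  m <- dplyr::left_join(
    ehr$measurements[ehr$measurements$patient_id %in% exposed &
                       ehr$measurements$test_id == test_id, ],
    ehr$reference_ranges, by = "test_id"
  )
  per_patient <- tapply(m$value > m$upper_limit, m$patient_id, any)
  expect_true(all(per_patient))
  expect_gt(length(per_patient), 0)
})

test_that("mapping and knowledge-base generation honours its contracts", {
  truth <- ground_truth(label_known = tibble::tibble(
    drug = c("etanercept", "abatacept"),
    term = c("Headache", "Rash")
  ))
  maps <- generate_mappings_and_labels(truth)
  expect_setequal(maps$label_kb$drug, c("etanercept", "abatacept"))
  expect_true(all(default_drug_table()$brand %in% maps$brand_map$brand))

  empty <- generate_mappings_and_labels(ground_truth())
  expect_equal(nrow(empty$label_kb), 0)

  # round-trip through the TSV serialization preserves the pair set
  path <- withr::local_tempfile(fileext = ".tsv")
  write_label_kb(maps$label_kb, path)
  back <- read_label_kb(path)
  expect_setequal(paste(back$drug, back$term),
                  paste(maps$label_kb$drug, maps$label_kb$term))

  bad <- ground_truth(label_known = tibble::tibble(
    drug = "etanercept", term = "Notaterm"
  ))
  expect_error(generate_mappings_and_labels(bad), "Notaterm")
})
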