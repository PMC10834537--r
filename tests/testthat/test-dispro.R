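no_map <- list(brand_map = tibble::tibble(brand = character(),
                                          generic = character()))

test_that("case/non-case counting follows the distinct-report contract", {
  srs <- tibble::tibble(
    report_id = c("r1", "r2", "r3", "r4"),
    drug_name = c("X", "X", "Y", "Y"),
    event_term = c("t", "u", "t", "u")
  )
  tab <- build_case_noncase(srs, no_map)
  xt <- tab[tab$drug == "X" & tab$event == "t", ]
  expect_equal(unlist(xt[c("a", "b", "c", "d")]),
               c(a = 1L, b = 1L, c = 1L, d = 1L))

  # one report with two drugs and one event contributes to both pairs
  multi <- tibble::tibble(
    report_id = c("r1", "r1"),
    drug_name = c("X", "Y"),
    event_term = c("t", "t")
  )
  tab2 <- build_case_noncase(multi, no_map)
  expect_equal(tab2$a, c(1L, 1L))

  # duplicated (report, drug, event) rows collapse before counting
  dup <- rbind(srs, srs[1, ])
  expect_equal(as.data.frame(build_case_noncase(dup, no_map)),
               as.data.frame(tab))
})

test_that("unmapped drug names error when a universe is declared", {
  srs <- tibble::tibble(report_id = "r1", drug_name = "mystery",
                        event_term = "t")
  expect_error(
    build_case_noncase(srs, no_map, drug_universe = c("X", "Y")),
    "mystery"
  )
})

test_that("report tables match a brute-force per-report scan", {
  set.seed(71)
  srs <- generate_srs(
    srs_config(n_reports = 2000L, brand_fraction = 0.3),
    seed = 72
  )
  bm <- distinct(default_drug_table(), brand, generic)
  tab <- build_case_noncase(srs, list(brand_map = bm))
  picks <- tab[sample.int(nrow(tab), 100), ]
  for (i in seq_len(nrow(picks))) {
    want <- oracle_srs_table(srs, picks$drug[i], picks$event[i],
                             brand_map = bm)
    expect_equal(unlist(picks[i, c("a", "b", "c", "d")]), want)
  }
})

test_that("disproportionality statistics match exact arithmetic", {
  unit <- dispro_stats(1, 1, 1, 1)
  expect_equal(unit$prr, 1)
  expect_equal(unit$ror, 1)
  expect_equal(unit$ic, 0)
  expect_false(unit$corrected)

  ex <- dispro_stats(2, 2, 1, 3)
  expect_equal(ex$prr, 2, tolerance = 1e-15)
  expect_equal(ex$ror, 3, tolerance = 1e-15)
  expect_equal(ex$ic, log2(16 / 12), tolerance = 1e-15)

  z <- dispro_stats(5, 0, 3, 9)
  expect_true(z$corrected)
  expect_equal(z$ror, (5.5 / 0.5) / (3.5 / 9.5), tolerance = 1e-15)
  expect_error(dispro_stats(0, 0, 0, 0), "all-zero")
})

test_that("sign coherence holds on random zero-free tables", {
  tabs <- random_tables(2000, seed = 73)
  st <- dispro_stats(tabs$a, tabs$b, tabs$c, tabs$d)
  det <- tabs$a * tabs$d - tabs$b * tabs$c
  nz <- det != 0
  expect_identical(st$prr[nz] > 1, det[nz] > 0)
  expect_identical(st$ror[nz] > 1, det[nz] > 0)
  expect_identical(st$ic[nz] > 0, det[nz] > 0)
})

test_that("the cumulative-mean rule turns posterior null probabilities into FDRs", {
  expect_equal(pvscreen:::fdr_from_posterior(c(0.01, 0.02, 0.30)),
               c(0.01, 0.015, 0.11))
  # non-decreasing in rank regardless of input order
  post <- c(0.30, 0.01, 0.02)
  fdr <- pvscreen:::fdr_from_posterior(post)
  expect_equal(fdr, c(0.11, 0.01, 0.015))
  set.seed(74)
  p <- runif(50)
  f <- pvscreen:::fdr_from_posterior(p)
  expect_true(all(diff(f[order(p)]) >= 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("an overwhelming single pair drives all three FDRs to zero", {
  tab <- tibble::tibble(drug = "X", event = "t",
                        a = 5000L, b = 100L, c = 100L, d = 50000L)
  expect_lt(fdr_rank(tab, "prr"), 1e-6)
  expect_lt(fdr_rank(tab, "ror"), 1e-6)
  expect_lt(fdr_rank(tab, "ic", mc_draws = 100000L, seed = 1), 1e-6)
})

test_that("wald p-values are monotone through Benjamini-Hochberg", {
  tabs <- random_tables(200, seed = 75)
  fdr <- fdr_rank(tabs, "prr")
  # recompute raw p-values independently and check rank agreement
  se <- sqrt(1 / tabs$a - 1 / (tabs$a + tabs$b) +
               1 / tabs$c - 1 / (tabs$c + tabs$d))
  p <- pnorm(log((tabs$a / (tabs$a + tabs$b)) /
                   (tabs$c / (tabs$c + tabs$d))) / se,
             lower.tail = FALSE)
  expect_equal(fdr, p.adjust(p, "BH"), tolerance = 1e-12)
  expect_true(all(fdr >= 0 & fdr <= 1))
})

test_that("the IC posterior is stable across Monte-Carlo seeds", {
  tabs <- tibble::tibble(
    drug = "X", event = paste0("t", 1:5),
    a = c(30L, 60L, 12L, 45L, 80L), b = c(200L, 500L, 90L, 310L, 400L),
    c = c(25L, 70L, 20L, 60L, 90L), d = c(1000L, 2000L, 600L, 1500L, 2500L)
  )
  p1 <- pvscreen:::ic_posterior_null(tabs$a, tabs$b, tabs$c, tabs$d,
                                     mc_draws = 100000L, seed = 1)
  p2 <- pvscreen:::ic_posterior_null(tabs$a, tabs$b, tabs$c, tabs$d,
                                     mc_draws = 100000L, seed = 2)
  expect_lt(max(abs(p1 - p2)), 0.01)
  expect_warning(fdr_rank(tabs, "ic", mc_draws = 500L), "noisy")
})

test_that("candidate annotation applies the any-of-three rule and handles absent pairs", {
  dispro <- structure(
    tibble::tibble(
      drug = c("X", "Y"), event = c("t", "u"), a = c(10L, 3L),
      prr = c(5, 0.8), ror = c(6, 0.7), ic = c(1.5, -0.2),
      corrected = FALSE,
      fdr_prr = c(0.2, 0.9), fdr_ror = c(0.3, 0.9), fdr_ic = c(0.01, 0.8),
      significant_any = c(TRUE, FALSE)
    ),
    threshold = 0.05, class = c("pv_dispro", "tbl_df", "tbl", "data.frame")
  )
  cands <- tibble::tibble(drug = c("X", "Y", "Z"), term = c("t", "u", "v"))
  ann <- validate_candidates(cands, dispro)
  expect_equal(ann$significant_any, c(TRUE, FALSE, FALSE))
  expect_equal(ann$in_srs, c(TRUE, TRUE, FALSE))
  expect_true(is.na(ann$prr[3]))
})
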