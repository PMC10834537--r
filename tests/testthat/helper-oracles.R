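# Independent oracle implementations used across test files.  These follow
# textbook formulas with different arithmetic paths (and explicit loops for
# counting) so agreement with the package is a genuine cross-check.

# Katz log-RR interval computed with an independent operation order.
oracle_rr_ci <- function(a, b, c, d, alpha = 0.05) {
  rr <- (a * (c + d)) / ((a + b) * c)
  z <- qnorm(1 - alpha / 2)
  var_log <- 1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)
  list(
    rr = rr,
    ci_low = rr * exp(-z * sqrt(var_log)),
    ci_high = rr * exp(z * sqrt(var_log))
  )
}

# PRR / ROR / IC as exact fractions (numerator/denominator kept separate).
oracle_dispro <- function(a, b, c, d) {
  n <- a + b + c + d
  list(
    prr = (a * (c + d)) / (c * (a + b)),
    ror = (a * d) / (b * c),
    ic = log2(a) + log2(n) - log2(a + c) - log2(a + b)
  )
}

# Brute-force registry 2x2 via an explicit loop over cases.
oracle_registry_table <- function(cases, drug, term) {
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(cases))) {
    on_drug <- cases$drug[i] == drug
    has_term <- term %in% cases$terms[[i]]
    if (on_drug && has_term) a <- a + 1L
    else if (on_drug) b <- b + 1L
    else if (has_term) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Brute-force case/non-case 2x2 via a per-report scan.
oracle_srs_table <- function(srs, drug, event, brand_map = NULL) {
  drug_name <- srs$drug_name
  if (!is.null(brand_map)) {
    hit <- match(drug_name, brand_map$brand)
    drug_name[!is.na(hit)] <- brand_map$generic[hit[!is.na(hit)]]
  }
  reports <- unique(srs$report_id)
  a <- b <- cc <- d <- 0L
  for (r in reports) {
    rows <- srs$report_id == r
    has_drug <- drug %in% drug_name[rows]
    has_event <- event %in% srs$event_term[rows]
    if (has_drug && has_event) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_event) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Random strictly-positive 2x2 tables.
random_tables <- function(n, seed, max_cell = 500L) {
  set.seed(seed)
  tibble::tibble(
    a = sample.int(max_cell, n, replace = TRUE),
    b = sample.int(max_cell, n, replace = TRUE),
    c = sample.int(max_cell, n, replace = TRUE),
    d = sample.int(max_cell, n, replace = TRUE)
  )
}

# A small random case fixture for counting oracles.
random_cases <- function(n_cases, n_drugs = 6L, n_terms = 12L, seed = 1L,
                         disease = "RA") {
  set.seed(seed)
  drugs <- paste0("drug", seq_len(n_drugs))
  terms <- paste0("term", seq_len(n_terms))
  tibble::tibble(
    case_id = sprintf("C%04d", seq_len(n_cases)),
    disease = disease,
    drug = sample(drugs, n_cases, replace = TRUE),
    terms = lapply(seq_len(n_cases), function(i) {
      k <- rbinom(1, 4, 0.35)
      sample(terms, k)
    })
  )
}

# A tiny hand-rolled registry exercising every selection rule.
tiny_registry <- function() {
  patients <- tibble::tibble(
    patient_id = c("P1", "P2", "P3", "P4"),
    disease = "RA",
    withdrawal_flag = c(FALSE, FALSE, FALSE, TRUE)
  )
  events <- tibble::tibble(
    event_id = c("E0", "E1", "E2", "E3", "E4"),
    patient_id = c("P1", "P1", "P2", "P3", "P4"),
    disease = "RA",
    phase = c("initial", "follow_up", "follow_up", "follow_up", "initial"),
    drug_brand_name = c("dx-orig", "dx-orig", "dx-bios1", "dy-orig",
                        "dy-orig"),
    drug_status = c(NA, "continued", "switched", "continued", NA)
  )
  adr_reports <- tibble::tibble(
    report_id = c("R1", "R2", "R3", "R4"),
    event_id = c("E1", "E1", "E2", "E3"),
    raw_term = c("HEADACHE", "RASH", "HEADACHE", "HEADACHE"),
    relatedness = c("related", "unrelated", "related", "indeterminate"),
    severity = "I", outcome = "resolved",
    is_lab_abnormality = FALSE
  )
  list(
    registry = structure(list(patients = patients, events = events,
                              adr_reports = adr_reports),
                         class = "pv_registry"),
    mappings = list(
      brand_map = tibble::tibble(
        brand = c("dx-orig", "dx-bios1", "dy-orig"),
        generic = c("drugx", "drugx", "drugy")
      ),
      term_map = tibble::tibble(
        raw_term = c("HEADACHE", "RASH"),
        preferred_term = c("Headache", "Rash"),
        is_lab = FALSE
      )
    )
  )
}
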