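#' Ground truth for synthetic pharmacovigilance datasets
#'
#' Bundles the embedded associations that the generators inject and the
#' downstream screens are expected to recover: registry risk ratios, SRS
#' reporting-rate ratios, laboratory excursion probabilities, and the
#' label-known pairs used by the exclusion stage.
#'
#' @param registry_signals Tibble with columns `disease`, `drug`, `term`,
#'   `rr` (risk ratio >= 1) for pairs embedded in the registry generator.
#' @param srs_signals Tibble with columns `drug`, `term`, `rrr`
#'   (reporting-rate ratio >= 1) for pairs embedded in the SRS generator.
#' @param lab_signals Tibble with columns `drug`, `signal_id`,
#'   `excursion_prob` in (0, 1] for pairs embedded in the EHR-lab generator.
#' @param label_known Tibble with columns `drug`, `term`: pairs treated as
#'   already documented in drug labels.
#' @return A `pv_ground_truth` list.
#' @export
ground_truth <- function(registry_signals = NULL, srs_signals = NULL,
                         lab_signals = NULL, label_known = NULL) {
  empty_pairs <- tibble(drug = character(), term = character())
  gt <- list(
    registry_signals = registry_signals %||%
      tibble(disease = character(), drug = character(),
             term = character(), rr = numeric()),
    srs_signals = srs_signals %||%
      tibble(drug = character(), term = character(), rrr = numeric()),
    lab_signals = lab_signals %||%
      tibble(drug = character(), signal_id = character(),
             excursion_prob = numeric()),
    label_known = label_known %||% empty_pairs
  )
  if (nrow(gt$registry_signals) && any(gt$registry_signals$rr < 1)) {
    abort("embedded registry risk ratios must be >= 1")
  }
  if (nrow(gt$srs_signals) && any(gt$srs_signals$rrr < 1)) {
    abort("embedded SRS reporting-rate ratios must be >= 1")
  }
  if (nrow(gt$lab_signals) &&
      any(gt$lab_signals$excursion_prob <= 0 | gt$lab_signals$excursion_prob > 1)) {
    abort("lab excursion probabilities must lie in (0, 1]")
  }
  structure(gt, class = "pv_ground_truth")
}

#' Default drug vocabulary for the synthetic registry
#'
#' Biologic DMARDs and targeted therapies prescribed for rheumatoid
#' arthritis (RA) and ankylosing spondylitis (AS); TNF inhibitors are shared
#' between the two diseases, mirroring real prescribing.  Each generic
#' carries an originator and a biosimilar brand so the brand-to-generic
#' normalisation step is always exercised.
#'
#' @return Tibble with columns `disease`, `generic`, `brand`.
#' @export
default_drug_table <- function() {
  ra <- c("etanercept", "infliximab", "adalimumab", "golimumab",
          "rituximab", "abatacept", "tocilizumab", "tofacitinib")
  as_ <- c("etanercept", "infliximab", "adalimumab", "golimumab",
           "secukinumab")
  per_disease <- function(disease, generics) {
    tidyr::expand_grid(
      disease = disease,
      generic = generics,
      suffix = c("orig", "bios1")
    ) |>
      mutate(brand = paste0(.data$generic, "-", .data$suffix)) |>
      select("disease", "generic", "brand")
  }
  bind_rows(per_disease("RA", ra), per_disease("AS", as_))
}

#' Default adverse-event term vocabulary
#'
#' A flat vocabulary of MedDRA-preferred-term style event names; laboratory
#' abnormality terms (the `"... increased"` / `"... decreased"` style) carry
#' `is_lab = TRUE`.  Raw terms (what a reporter would type) are the
#' upper-cased preferred terms, so the raw-to-preferred normalisation step is
#' non-trivial but invertible.
#'
#' @param n_terms Number of clinical (non-laboratory) terms to keep.
#' @param n_lab Number of laboratory abnormality terms to keep.
#' @return Tibble with columns `preferred_term`, `raw_term`, `is_lab`.
#' @export
default_term_table <- function(n_terms = 45, n_lab = 15) {
  clinical <- c(
    "Nasopharyngitis", "Upper respiratory tract infection", "Headache",
    "Nausea", "Rash", "Pruritus", "Arthralgia", "Dizziness", "Fatigue",
    "Urticaria", "Herpes zoster", "Pneumonia", "Urinary tract infection",
    "Injection site reaction", "Infusion related reaction", "Alopecia",
    "Oral ulceration", "Dyspepsia", "Diarrhoea", "Constipation",
    "Hypertension", "Insomnia", "Depression", "Anxiety", "Cough",
    "Dyspnoea", "Back pain", "Myalgia", "Peripheral oedema", "Pyrexia",
    "Conjunctivitis", "Dry eye", "Cataract", "Osteoporosis", "Anaemia",
    "Leukopenia", "Thrombocytopenia", "Interstitial lung disease",
    "Latent tuberculosis", "Cellulitis", "Sinusitis", "Gastritis",
    "Gastroesophageal reflux disease", "Vertigo", "Tinnitus",
    "Stomatitis", "Bronchitis", "Folliculitis", "Paraesthesia",
    "Palpitations"
  )
  lab <- c(
    "Alanine aminotransferase increased", "Aspartate aminotransferase increased",
    "Blood creatinine increased", "Blood creatinine decreased",
    "Blood glucose increased", "Blood cholesterol increased",
    "Blood triglycerides increased", "Haemoglobin decreased",
    "White blood cell count decreased", "White blood cell count increased",
    "Platelet count decreased", "Platelet count increased",
    "Blood uric acid increased", "Blood alkaline phosphatase increased",
    "Low density lipoprotein increased", "Neutrophil count decreased",
    "Lymphocyte count decreased", "Blood bilirubin increased"
  )
  if (n_terms > length(clinical) || n_lab > length(lab)) {
    abort("requested vocabulary larger than the built-in term pool")
  }
  out <- bind_rows(
    tibble(preferred_term = clinical[seq_len(n_terms)], is_lab = FALSE),
    tibble(preferred_term = lab[seq_len(n_lab)], is_lab = TRUE)
  )
  mutate(out, raw_term = toupper(.data$preferred_term)) |>
    select("raw_term", "preferred_term", "is_lab")
}

#' Configuration for the synthetic registry generator
#'
#' Defaults emulate the shape of a nationwide biologics registry cohort:
#' roughly 2,300 RA and 1,900 AS patients, about three yearly follow-up
#' visits each, ~3% consent withdrawal, and a majority of follow-ups on a
#' continued (unchanged) agent.
#'
#' @param n_patients Named integer vector of patients per disease stratum.
#' @param n_followups Follow-up visits per non-withdrawn patient (yearly).
#' @param withdrawal_fraction Probability a patient withdraws consent.
#' @param status_probs Named probabilities over follow-up drug statuses
#'   `continued`, `switched`, `discontinued`, `other`.
#' @param baseline_prob Per-case probability that any given term is reported
#'   with relatedness in {related, indeterminate} for a non-embedded pair.
#' @param unrelated_prob Per-case probability of an additional
#'   relatedness = "unrelated" report of a term (noise that the relatedness
#'   filter must remove).
#' @param relatedness_probs Mixture over {related, indeterminate} for
#'   injected reports.
#' @param drug_table Tibble `disease`, `generic`, `brand`
#'   (see [default_drug_table()]).
#' @param term_table Tibble `raw_term`, `preferred_term`, `is_lab`
#'   (see [default_term_table()]).
#' @return A `pv_registry_config` list.
#' @export
registry_config <- function(n_patients = c(RA = 2279L, AS = 1940L),
                            n_followups = 3L,
                            withdrawal_fraction = 0.03,
                            status_probs = c(continued = 0.6, switched = 0.2,
                                             discontinued = 0.15, other = 0.05),
                            baseline_prob = 0.02,
                            unrelated_prob = 0.005,
                            relatedness_probs = c(related = 0.7,
                                                  indeterminate = 0.3),
                            drug_table = default_drug_table(),
                            term_table = default_term_table()) {
  assert_prob(withdrawal_fraction, "withdrawal_fraction")
  assert_prob(baseline_prob, "baseline_prob")
  assert_prob(unrelated_prob, "unrelated_prob")
  if (abs(sum(status_probs) - 1) > 1e-8) {
    abort("`status_probs` must sum to 1")
  }
  if (abs(sum(relatedness_probs) - 1) > 1e-8) {
    abort("`relatedness_probs` must sum to 1")
  }
  structure(
    list(
      n_patients = n_patients, n_followups = as.integer(n_followups),
      withdrawal_fraction = withdrawal_fraction, status_probs = status_probs,
      baseline_prob = baseline_prob, unrelated_prob = unrelated_prob,
      relatedness_probs = relatedness_probs,
      drug_table = drug_table, term_table = term_table
    ),
    class = "pv_registry_config"
  )
}

check_registry_truth <- function(config, truth) {
  if (nrow(truth$registry_signals) == 0L) return(invisible(truth))
  sig <- truth$registry_signals
  known <- distinct(config$drug_table, .data$disease, .data$generic)
  bad_drug <- anti_join(sig, known,
                        by = c(disease = "disease", drug = "generic"))
  if (nrow(bad_drug)) {
    abort_unmapped("embedded (disease, drug) pair",
                   paste0(bad_drug$disease, ":", bad_drug$drug))
  }
  bad_term <- sig$term[!sig$term %in% config$term_table$preferred_term]
  if (length(bad_term)) abort_unmapped("embedded term", bad_term)
  if (any(config$baseline_prob * sig$rr > 1)) {
    abort("baseline_prob x risk_ratio exceeds 1 for an embedded pair")
  }
  invisible(truth)
}

#' Generate a synthetic drug-registry dataset
#'
#' Emulates a biologics registry: patients enrol into one disease stratum on
#' one (brand-named) agent, contribute yearly follow-up visits, and each
#' follow-up carries adverse-event reports with relatedness, severity and
#' outcome labels.  ADR occurrence is sampled independently per follow-up
#' case (each follow-up is an independent case in the downstream analysis).
#' For an embedded signal with risk ratio `rr`, the per-case probability of a
#' related/indeterminate report of the term is `rr * baseline_prob`;
#' non-embedded pairs occur at `baseline_prob`.  Unrelated reports are added
#' as noise at `unrelated_prob`.
#'
#' @param config A [registry_config()].
#' @param truth A [ground_truth()] (embedded registry signals; may be empty).
#' @param seed Integer master seed; identical (config, truth, seed) gives
#'   byte-identical output.
#' @return A `pv_registry` list of tibbles: `patients` (patient_id, disease,
#'   withdrawal_flag), `events` (event_id, patient_id, disease, phase,
#'   drug_brand_name, drug_status), `adr_reports` (report_id, event_id,
#'   raw_term, relatedness, severity, outcome, is_lab_abnormality).
#' @export
generate_registry <- function(config = registry_config(),
                              truth = ground_truth(), seed = 1L) {
  check_registry_truth(config, truth)
  set.seed(child_seed(seed, "registry"))
  statuses <- names(config$status_probs)
  out <- purrr::map(names(config$n_patients), function(dis) {
    n <- config$n_patients[[dis]]
    drugs <- filter(config$drug_table, .data$disease == dis)
    if (nrow(drugs) == 0L) abort(paste0("no drugs configured for ", dis))
    patients <- tibble(
      patient_id = sprintf("%s-%05d", dis, seq_len(n)),
      disease = dis,
      withdrawal_flag = runif(n) < config$withdrawal_fraction,
      brand = sample(drugs$brand, n, replace = TRUE)
    )
    initial <- tibble(
      patient_id = patients$patient_id, disease = dis, phase = "initial",
      drug_brand_name = patients$brand, drug_status = NA_character_
    )
    active <- filter(patients, !.data$withdrawal_flag)
    fu <- tidyr::expand_grid(
      patient_id = active$patient_id,
      visit = seq_len(config$n_followups)
    ) |>
      left_join(select(active, "patient_id", "brand"), by = "patient_id") |>
      mutate(
        disease = dis, phase = "follow_up",
        drug_status = sample(statuses, n(), replace = TRUE,
                             prob = config$status_probs)
      ) |>
      select("patient_id", "disease", "phase",
             drug_brand_name = "brand", "drug_status")
    events <- bind_rows(initial, fu)
    list(patients = select(patients, -"brand"), events = events)
  })
  patients <- bind_rows(purrr::map(out, "patients"))
  events <- bind_rows(purrr::map(out, "events")) |>
    mutate(event_id = sprintf("E%06d", row_number())) |>
    relocate("event_id")

  # sample reports on follow-up events only (interim-period ADRs)
  brand_gen <- distinct(config$drug_table, .data$brand, .data$generic)
  fu_events <- filter(events, .data$phase == "follow_up") |>
    left_join(brand_gen, by = c(drug_brand_name = "brand"))
  terms <- config$term_table
  sig <- truth$registry_signals
  inject <- purrr::map(seq_len(nrow(terms)), function(i) {
    pt <- terms$preferred_term[i]
    p <- rep(config$baseline_prob, nrow(fu_events))
    hit <- filter(sig, .data$term == pt)
    if (nrow(hit)) {
      key <- paste(fu_events$disease, fu_events$generic)
      rr <- setNames(hit$rr, paste(hit$disease, hit$drug))
      boost <- rr[key]
      p <- p * ifelse(is.na(boost), 1, boost)
    }
    keep <- runif(nrow(fu_events)) < p
    noise <- runif(nrow(fu_events)) < config$unrelated_prob
    bind_rows(
      tibble(event_id = fu_events$event_id[keep], raw_term = terms$raw_term[i],
             relatedness = sample(names(config$relatedness_probs), sum(keep),
                                  replace = TRUE,
                                  prob = config$relatedness_probs),
             is_lab_abnormality = terms$is_lab[i]),
      tibble(event_id = fu_events$event_id[noise], raw_term = terms$raw_term[i],
             relatedness = "unrelated",
             is_lab_abnormality = terms$is_lab[i])
    )
  })
  reports <- bind_rows(inject)
  reports <- reports[order(reports$event_id, reports$raw_term,
                           reports$relatedness), , drop = FALSE]
  reports <- mutate(
    reports,
    report_id = sprintf("R%07d", row_number()),
    severity = sample(c("I", "II", "III"), n(), replace = TRUE,
                      prob = c(0.7, 0.25, 0.05)),
    outcome = sample(c("resolved", "not_resolved", "resolved_with_sequelae",
                       "unknown", "death"), n(), replace = TRUE,
                     prob = c(0.6, 0.2, 0.05, 0.145, 0.005))
  ) |>
    relocate("report_id") |>
    as_tibble()
  structure(
    list(patients = patients, events = events, adr_reports = reports),
    class = "pv_registry"
  )
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' @param n_reports Number of reports to generate.
#' @param drug_probs Named marginal probabilities over generic drug names
#'   (must sum to 1); defaults to a uniform distribution over the registry
#'   drugs plus five background ("other") drugs.
#' @param event_probs Named marginal probabilities over event terms
#'   (must sum to 1); defaults to uniform over [default_term_table()] terms.
#' @param events_per_report Mean number of event mentions per report.
#' @param multi_drug_prob Probability a report carries a second drug.
#' @param brand_fraction Fraction of drug mentions recorded under a brand
#'   name (requiring brand-to-generic mapping downstream).
#' @param drug_table Brand vocabulary used for brand-name substitution.
#' @return A `pv_srs_config` list.
#' @export
srs_config <- function(n_reports = 50000L,
                       drug_probs = NULL,
                       event_probs = NULL,
                       events_per_report = 1.5,
                       multi_drug_prob = 0.2,
                       brand_fraction = 0.3,
                       drug_table = default_drug_table()) {
  if (is.null(drug_probs)) {
    gen <- unique(c(drug_table$generic,
                    paste0("backgrounddrug", 1:5)))
    drug_probs <- setNames(rep(1 / length(gen), length(gen)), gen)
  }
  if (is.null(event_probs)) {
    ev <- default_term_table()$preferred_term
    event_probs <- setNames(rep(1 / length(ev), length(ev)), ev)
  }
  if (abs(sum(drug_probs) - 1) > 1e-6) abort("`drug_probs` must sum to 1")
  if (abs(sum(event_probs) - 1) > 1e-6) abort("`event_probs` must sum to 1")
  assert_prob(multi_drug_prob, "multi_drug_prob")
  assert_prob(brand_fraction, "brand_fraction")
  structure(
    list(n_reports = as.integer(n_reports), drug_probs = drug_probs,
         event_probs = event_probs, events_per_report = events_per_report,
         multi_drug_prob = multi_drug_prob, brand_fraction = brand_fraction,
         drug_table = drug_table),
    class = "pv_srs_config"
  )
}

#' Generate a synthetic spontaneous-report (SRS) dataset
#'
#' One row per (report, drug, event) mention; a report may carry multiple
#' drugs and multiple events.  For an embedded pair with reporting-rate
#' ratio `rrr`, the probability of the event being mentioned on a report is
#' `rrr` times the background mention probability whenever the report
#' carries the drug, so P(event | drug) = rrr x P(event | other drugs).  A
#' configurable fraction of drug mentions use brand names.
#'
#' @param config An [srs_config()].
#' @param truth A [ground_truth()] (embedded SRS signals; may be empty).
#' @param seed Integer master seed.
#' @return A `pv_srs` tibble with columns `report_id`, `drug_name`,
#'   `event_term`.
#' @export
generate_srs <- function(config = srs_config(), truth = ground_truth(),
                         seed = 1L) {
  sig <- truth$srs_signals
  if (nrow(sig)) {
    bad_drug <- sig$drug[!sig$drug %in% names(config$drug_probs)]
    if (length(bad_drug)) abort_unmapped("embedded SRS drug", bad_drug)
    bad_term <- sig$term[!sig$term %in% names(config$event_probs)]
    if (length(bad_term)) abort_unmapped("embedded SRS term", bad_term)
    pmax_ <- config$events_per_report *
      config$event_probs[sig$term] * sig$rrr
    if (any(pmax_ > 1)) {
      abort("events_per_report x event_prob x rrr exceeds 1 for an embedded pair")
    }
  }
  set.seed(child_seed(seed, "srs"))
  n <- config$n_reports
  if (n == 0L) {
    return(structure(
      tibble(report_id = character(), drug_name = character(),
             event_term = character()),
      class = c("pv_srs", class(tibble()))
    ))
  }
  drugs1 <- sample(names(config$drug_probs), n, replace = TRUE,
                   prob = config$drug_probs)
  second <- runif(n) < config$multi_drug_prob
  drugs2 <- rep(NA_character_, n)
  drugs2[second] <- sample(names(config$drug_probs), sum(second),
                           replace = TRUE, prob = config$drug_probs)
  drugs2[!is.na(drugs2) & drugs2 == drugs1] <- NA_character_

  ev_names <- names(config$event_probs)
  base_p <- config$events_per_report * config$event_probs
  if (any(base_p > 1)) abort("events_per_report x event_prob exceeds 1")
  mention <- purrr::map(seq_along(ev_names), function(i) {
    p <- rep(base_p[[i]], n)
    hit <- filter(sig, .data$term == ev_names[[i]])
    if (nrow(hit)) {
      rrr <- setNames(hit$rrr, hit$drug)
      m1 <- rrr[drugs1]; m2 <- rrr[drugs2]
      mult <- pmax(ifelse(is.na(m1), 1, m1), ifelse(is.na(m2), 1, m2))
      p <- p * mult
    }
    which(runif(n) < p)
  })
  mention_report <- unlist(mention, use.names = FALSE)
  mention_event <- rep(ev_names, lengths(mention))
  ord <- order(mention_report, mention_event)
  ev_per_report <- split(mention_event[ord],
                         factor(mention_report[ord], levels = seq_len(n)))
  empty <- which(lengths(ev_per_report) == 0L)
  if (length(empty)) {
    fill <- sample(ev_names, length(empty), replace = TRUE,
                   prob = config$event_probs)
    ev_per_report[empty] <- as.list(fill)
  }

  report_ids <- sprintf("S%07d", seq_len(n))
  ne <- lengths(ev_per_report)
  sel2 <- which(!is.na(drugs2))
  rows <- bind_rows(
    tibble(report_id = rep(report_ids, ne),
           drug_name = rep(drugs1, ne),
           event_term = unlist(ev_per_report, use.names = FALSE)),
    tibble(report_id = rep(report_ids[sel2], ne[sel2]),
           drug_name = rep(drugs2[sel2], ne[sel2]),
           event_term = unlist(ev_per_report[sel2], use.names = FALSE))
  ) |>
    arrange(.data$report_id, .data$drug_name, .data$event_term)
  # brand-name substitution on a fraction of drug mentions
  brands <- distinct(config$drug_table, .data$generic, .data$brand) |>
    group_by(.data$generic) |>
    mutate(slot = row_number()) |>
    ungroup()
  n_brands <- setNames(
    tabulate(factor(brands$generic, levels = unique(brands$generic))),
    unique(brands$generic)
  )
  brand_by_key <- setNames(brands$brand,
                           paste(brands$generic, brands$slot))
  use_brand <- runif(nrow(rows)) < config$brand_fraction
  idx <- which(use_brand & rows$drug_name %in% names(n_brands))
  if (length(idx)) {
    choice <- ceiling(runif(length(idx)) * n_brands[rows$drug_name[idx]])
    rows$drug_name[idx] <-
      unname(brand_by_key[paste(rows$drug_name[idx], choice)])
  }
  structure(rows, class = c("pv_srs", class(rows)))
}

#' Default laboratory-signal catalog (synthetic)
#'
#' A synthetic stand-in for a laboratory ADR signal catalog: 102 signals
#' over 51 tests, partitioned into 38 above-upper-limit, 39
#' below-lower-limit and 25 outside-normal-range definitions.  Reference
#' ranges are synthetic round numbers.
#'
#' @return List with `catalog` (signal_id, test_id, direction) and
#'   `reference_ranges` (test_id, lower_limit, upper_limit).
#' @export
default_lab_catalog <- function() {
  n_tests <- 51L
  tests <- sprintf("LT%03d", seq_len(n_tests))
  directions <- c(rep("above_upper", 38L), rep("below_lower", 39L),
                  rep("outside_range", 25L))
  catalog <- tibble(
    signal_id = sprintf("SIG%03d", seq_along(directions)),
    test_id = rep(tests, length.out = length(directions)),
    direction = directions
  )
  ranges <- tibble(
    test_id = tests,
    lower_limit = 10 * seq_len(n_tests),
    upper_limit = 10 * seq_len(n_tests) + 20
  )
  list(catalog = catalog, reference_ranges = ranges)
}

#' Configuration for the synthetic EHR laboratory generator
#'
#' @param n_patients Named integer vector of patients per disease code.
#' @param drug_codes Character vector of drug codes patients may be exposed
#'   to (one exposure per patient).
#' @param catalog,reference_ranges Laboratory-signal catalog and reference
#'   ranges (see [default_lab_catalog()]).
#' @param tests_per_patient Number of distinct tests measured per patient.
#' @param measurements_per_test Measurements per measured test.
#' @param background_abnormal_prob Probability any measurement is abnormal
#'   (outside the range, random side) absent an embedded signal.
#' @param window_days Measurement dates fall uniformly in this many days
#'   after exposure start.
#' @return A `pv_ehr_config` list.
#' @export
ehr_config <- function(n_patients = c(RA = 1411L, AS = 656L),
                       drug_codes = unique(default_drug_table()$generic),
                       catalog = default_lab_catalog()$catalog,
                       reference_ranges = default_lab_catalog()$reference_ranges,
                       tests_per_patient = 12L,
                       measurements_per_test = 3L,
                       background_abnormal_prob = 0.02,
                       window_days = 365L) {
  if (nrow(catalog) == 0L) abort("laboratory catalog must be non-empty")
  if (!all(catalog$direction %in%
           c("above_upper", "below_lower", "outside_range"))) {
    abort("catalog directions must be above_upper, below_lower or outside_range")
  }
  missing_rng <- setdiff(catalog$test_id, reference_ranges$test_id)
  if (length(missing_rng)) abort_unmapped("catalog test_id", missing_rng)
  if (any(reference_ranges$lower_limit >= reference_ranges$upper_limit)) {
    abort("reference ranges must satisfy lower_limit < upper_limit")
  }
  assert_prob(background_abnormal_prob, "background_abnormal_prob")
  structure(
    list(n_patients = n_patients, drug_codes = drug_codes, catalog = catalog,
         reference_ranges = reference_ranges,
         tests_per_patient = as.integer(tests_per_patient),
         measurements_per_test = as.integer(measurements_per_test),
         background_abnormal_prob = background_abnormal_prob,
         window_days = as.integer(window_days)),
    class = "pv_ehr_config"
  )
}

abnormal_value <- function(direction, lower, upper, u) {
  n <- max(length(direction), length(lower), length(upper), length(u))
  direction <- rep_len(direction, n)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  u <- rep_len(u, n)
  span <- upper - lower
  above <- upper + (0.05 + 0.45 * u) * span
  below <- lower - (0.05 + 0.45 * u) * span
  go_above <- direction == "above_upper" |
    (direction == "outside_range" & u < 0.5)
  ifelse(go_above, above, below)
}

#' Generate a synthetic EHR laboratory dataset
#'
#' One exposure per patient (a disease code and a drug code with a start
#' date) and a panel of laboratory measurements dated within a window after
#' exposure start.  Unexposed-to-a-given-drug comparisons come from patients
#' on the other catalog drugs.  Values are drawn inside the reference range
#' except: (i) with `background_abnormal_prob` a measurement falls outside
#' the range on a random side; (ii) for an embedded (drug, lab-signal) pair,
#' each exposed patient independently shows an excursion in the signal's
#' direction with the embedded probability (forced onto their first
#' post-exposure measurement of the test).
#'
#' @param config An [ehr_config()].
#' @param truth A [ground_truth()] (embedded lab signals; may be empty).
#' @param seed Integer master seed.
#' @return A `pv_ehr` list of tibbles: `exposures` (patient_id,
#'   disease_code, drug_code, start_date), `measurements` (patient_id,
#'   test_id, value, date), `reference_ranges`.
#' @export
generate_ehr_lab <- function(config = ehr_config(), truth = ground_truth(),
                             seed = 1L) {
  sig <- truth$lab_signals
  if (nrow(sig)) {
    bad <- sig$signal_id[!sig$signal_id %in% config$catalog$signal_id]
    if (length(bad)) abort_unmapped("embedded lab signal_id", bad)
    bad_drug <- sig$drug[!sig$drug %in% config$drug_codes]
    if (length(bad_drug)) abort_unmapped("embedded lab drug", bad_drug)
  }
  set.seed(child_seed(seed, "ehr"))
  origin <- as.Date("2015-01-01")
  pats <- purrr::imap(config$n_patients, function(n, dis) {
    tibble(
      patient_id = sprintf("P-%s-%05d", dis, seq_len(n)),
      disease_code = dis,
      drug_code = sample(config$drug_codes, n, replace = TRUE),
      start_date = origin + sample.int(1000L, n, replace = TRUE)
    )
  }) |> bind_rows()

  tests <- config$reference_ranges$test_id
  k <- min(config$tests_per_patient, length(tests))
  per_pat_tests <- purrr::map(seq_len(nrow(pats)),
                              function(i) sample(tests, k))
  meas <- tibble(
    patient_id = rep(pats$patient_id, each = k * config$measurements_per_test),
    drug_code = rep(pats$drug_code, each = k * config$measurements_per_test),
    start_date = rep(pats$start_date, each = k * config$measurements_per_test),
    test_id = unlist(purrr::map(per_pat_tests,
                                function(t) rep(t, each = config$measurements_per_test))),
    offset = sample.int(config$window_days,
                        nrow(pats) * k * config$measurements_per_test,
                        replace = TRUE)
  ) |>
    left_join(config$reference_ranges, by = "test_id") |>
    mutate(
      date = .data$start_date + .data$offset,
      u = runif(n()),
      value = .data$lower_limit +
        (0.05 + 0.9 * .data$u) * (.data$upper_limit - .data$lower_limit)
    )
  # background abnormalities
  bg <- runif(nrow(meas)) < config$background_abnormal_prob
  if (any(bg)) {
    meas$value[bg] <- abnormal_value("outside_range",
                                     meas$lower_limit[bg],
                                     meas$upper_limit[bg],
                                     runif(sum(bg)))
  }
  # embedded drug-triggered excursions: per-patient Bernoulli, forced onto
  # the first post-exposure measurement of the signal's test
  if (nrow(sig)) {
    sig2 <- left_join(sig, config$catalog, by = "signal_id")
    for (i in seq_len(nrow(sig2))) {
      pat_hit <- pats$patient_id[pats$drug_code == sig2$drug[i]]
      pat_hit <- pat_hit[runif(length(pat_hit)) < sig2$excursion_prob[i]]
      if (!length(pat_hit)) next
      rows <- which(meas$patient_id %in% pat_hit &
                      meas$test_id == sig2$test_id[i])
      if (!length(rows)) next
      first_rows <- rows[!duplicated(meas$patient_id[rows])]
      meas$value[first_rows] <- abnormal_value(
        sig2$direction[i], meas$lower_limit[first_rows],
        meas$upper_limit[first_rows], runif(length(first_rows))
      )
    }
  }
  structure(
    list(
      exposures = select(pats, "patient_id", "disease_code", "drug_code",
                         "start_date"),
      measurements = select(meas, "patient_id", "test_id", "value", "date"),
      reference_ranges = config$reference_ranges
    ),
    class = "pv_ehr"
  )
}

#' Build mapping tables and the label knowledge base
#'
#' Produces the brand-to-generic table covering every brand either generator
#' can emit, the raw-term-to-preferred-term table, and the label knowledge
#' base equal to the ground truth's label-known pairs.
#'
#' @param truth A [ground_truth()].
#' @param drug_table Tibble `disease`, `generic`, `brand`.
#' @param term_table Tibble `raw_term`, `preferred_term`, `is_lab`.
#' @return List with tibbles `brand_map` (brand, generic), `term_map`
#'   (raw_term, preferred_term, is_lab), `label_kb` (drug, term, provenance).
#' @export
generate_mappings_and_labels <- function(truth,
                                         drug_table = default_drug_table(),
                                         term_table = default_term_table()) {
  if (nrow(drug_table) == 0L || nrow(term_table) == 0L) {
    abort("vocabularies must be non-empty")
  }
  kb <- truth$label_known
  bad <- kb$term[!kb$term %in% term_table$preferred_term]
  if (length(bad)) abort_unmapped("label-known term", bad)
  list(
    brand_map = distinct(drug_table, .data$brand, .data$generic),
    term_map = distinct(term_table, .data$raw_term, .data$preferred_term,
                        .data$is_lab),
    label_kb = mutate(distinct(kb, .data$drug, .data$term),
                      provenance = "label knowledge base")
  )
}
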