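#' Pair design of the shipped demonstration fixture
#'
#' The demo datasets are constructed deterministically (by direct placement
#' of counts, not by sampling) so that the flow shape of the analysis is a
#' set-arithmetic property of the fixture: 51 significant registry pairs in
#' the RA stratum and 36 in AS; 16 and 10 of them label-known, leaving 35
#' and 26 novel candidates; 13 and 6 of those confirmed by the
#' spontaneous-report screen; 5 confirmed pairs shared between the strata
#' (TNF inhibitors are prescribed in both diseases), so the merged final
#' signal set has 8 + 1 + 5 = 14 members.
#'
#' @return A tibble with columns `drug`, `term`, `stratum` (`RA`, `AS` or
#'   `both`), and `role` (`confirmed`, `unconfirmed`, or `label_known`).
#'   `confirmed` pairs are registry-significant, label-novel and
#'   SRS-significant; `unconfirmed` pairs are registry-significant and
#'   novel but weak in the SRS; `label_known` pairs are
#'   registry-significant but present in the label knowledge base.
#' @export
demo_design <- function() {
  pool <- default_term_table(50, 18)$preferred_term
  ra_drugs <- c("etanercept", "infliximab", "adalimumab", "golimumab",
                "rituximab", "abatacept", "tocilizumab", "tofacitinib")
  as_drugs <- c("etanercept", "infliximab", "adalimumab", "golimumab")
  shared_confirmed <- tibble(
    drug = c("etanercept", "infliximab", "adalimumab", "golimumab",
             "etanercept"),
    term = c("Uveitis", "Psoriasiform dermatitis", "Optic neuritis",
             "Demyelination", "Sarcoidosis"),
    stratum = "both", role = "confirmed"
  )
  ra_confirmed <- tibble(
    drug = c("adalimumab", "golimumab", "abatacept", "abatacept",
             "rituximab", "tocilizumab", "tocilizumab", "tofacitinib"),
    term = c("Osteonecrosis", "Bronchiectasis", "Glaucoma", "Hearing loss",
             "Cholelithiasis", "Thyroiditis", "Raynaud's phenomenon",
             "Blood fibrinogen increased"),
    stratum = "RA", role = "confirmed"
  )
  as_confirmed <- tibble(
    drug = "golimumab", term = "Iritis", stratum = "AS", role = "confirmed"
  )
  ra_unconfirmed <- tibble(
    drug = rep(ra_drugs, length.out = 22L),
    term = pool[1:22], stratum = "RA", role = "unconfirmed"
  )
  as_unconfirmed <- tibble(
    drug = rep(as_drugs, length.out = 20L),
    term = pool[23:42], stratum = "AS", role = "unconfirmed"
  )
  ra_known <- tibble(
    drug = rep(ra_drugs, length.out = 16L),
    term = pool[43:58], stratum = "RA", role = "label_known"
  )
  as_known <- tibble(
    drug = rep(as_drugs, length.out = 10L),
    term = pool[59:68], stratum = "AS", role = "label_known"
  )
  bind_rows(shared_confirmed, ra_confirmed, as_confirmed,
            ra_unconfirmed, as_unconfirmed, ra_known, as_known)
}

demo_noise_terms <- function() {
  c("Seasonal allergy", "Muscle strain", "Contusion")
}

demo_term_table <- function() {
  design <- demo_design()
  base <- default_term_table(50, 18)
  lab_extra <- "Blood fibrinogen increased"
  all_terms <- unique(c(design$term, base$preferred_term,
                        demo_noise_terms(), "Procedural pain",
                        "Device related infection"))
  tibble(
    preferred_term = all_terms,
    raw_term = toupper(all_terms),
    is_lab = all_terms %in% c(base$preferred_term[base$is_lab], lab_extra)
  ) |>
    select("raw_term", "preferred_term", "is_lab")
}

# One disease stratum of the demo registry, built by direct placement:
# each significant pair gets a = 12 cases on its drug and c = 4 single
# occurrences spread over four other drugs (below the min_count, so no
# spurious pair is evaluated); noise terms occur at identical rates on
# every drug (RR exactly 1).  Filter-exercising decoys: unrelated-only
# reports, withdrawn patients, and non-continued follow-ups carrying a
# would-be signal.
demo_stratum_registry <- function(dis, drugs, sig_pairs, n_per_drug = 400L) {
  cases <- tidyr::expand_grid(drug = drugs, idx = seq_len(n_per_drug)) |>
    mutate(
      disease = dis,
      patient_id = sprintf("%s-%s-%03d", dis, .data$drug, .data$idx),
      event_id = sprintf("FU-%s-%s-%03d", dis, .data$drug, .data$idx),
      brand = paste0(.data$drug,
                     if_else(.data$idx %% 2L == 1L, "-orig", "-bios1"))
    )
  assign_rows <- purrr::map(seq_len(nrow(sig_pairs)), function(k) {
    dr <- sig_pairs$drug[k]; tm <- sig_pairs$term[k]
    others <- setdiff(drugs, dr)
    spread <- others[(k - 1L + 0:3) %% length(others) + 1L]
    bind_rows(
      tibble(drug = dr, idx = 1:12, term = tm),
      tibble(drug = unique(spread)[1:4], idx = 200L + k, term = tm)
    )
  }) |> bind_rows()
  noise_rows <- tidyr::expand_grid(drug = drugs,
                                   term = demo_noise_terms(),
                                   idx = 101:105)
  related_rows <- bind_rows(assign_rows, noise_rows) |>
    mutate(relatedness = if_else(.data$idx %% 2L == 1L,
                                 "related", "indeterminate"))
  decoy_rows <- tibble(drug = drugs[1], idx = 1:50,
                       term = "Procedural pain", relatedness = "unrelated")
  report_rows <- bind_rows(related_rows, decoy_rows) |>
    inner_join(select(cases, "drug", "idx", "event_id"),
               by = c("drug", "idx"))

  withdrawn <- tibble(
    patient_id = sprintf("%s-wd-%03d", dis, 1:30),
    disease = dis, withdrawal_flag = TRUE,
    brand = paste0(drugs[1], "-orig")
  )
  switched <- tibble(
    patient_id = sprintf("%s-sw-%03d", dis, 1:60),
    disease = dis, withdrawal_flag = FALSE,
    brand = paste0(drugs[(0:59 %% length(drugs)) + 1L], "-orig"),
    status = c("switched", "discontinued", "other")[(0:59 %% 3L) + 1L],
    event_id = sprintf("FU-%s-sw-%03d", dis, 1:60)
  )
  patients <- bind_rows(
    tibble(patient_id = cases$patient_id, disease = dis,
           withdrawal_flag = FALSE),
    select(withdrawn, "patient_id", "disease", "withdrawal_flag"),
    tibble(patient_id = switched$patient_id, disease = dis,
           withdrawal_flag = FALSE)
  )
  events <- bind_rows(
    # initial enrollment for everyone
    tibble(event_id = paste0("IN-", patients$patient_id),
           patient_id = patients$patient_id, disease = dis,
           phase = "initial",
           drug_brand_name = c(cases$brand, withdrawn$brand, switched$brand),
           drug_status = NA_character_),
    tibble(event_id = cases$event_id, patient_id = cases$patient_id,
           disease = dis, phase = "follow_up",
           drug_brand_name = cases$brand, drug_status = "continued"),
    tibble(event_id = switched$event_id, patient_id = switched$patient_id,
           disease = dis, phase = "follow_up",
           drug_brand_name = switched$brand, drug_status = switched$status)
  )
  switched_reports <- tibble(event_id = switched$event_id,
                             term = "Device related infection",
                             relatedness = "related")
  reports <- bind_rows(
    select(report_rows, "event_id", "term", "relatedness"),
    switched_reports
  )
  list(patients = patients, events = events, reports = reports)
}

#' Build the shipped demonstration datasets
#'
#' Constructs the registry, spontaneous-report and EHR laboratory demo
#' datasets together with their mapping tables, label knowledge base and
#' ground truth.  The registry and SRS parts are fully deterministic (see
#' [demo_design()]); only the EHR laboratory part is sampled, from the
#' given seed.
#'
#' @param seed Integer seed for the EHR laboratory part.
#' @return List with elements `registry`, `srs`, `ehr`, `mappings`
#'   (brand_map, term_map), `label_kb`, `catalog`, `lab_term_map`
#'   (signal_id to preferred term, for annotating final signals), `truth`
#'   (a [ground_truth()]), and `design` (the [demo_design()] table).
#' @export
build_demo <- function(seed = 20240201L) {
  design <- demo_design()
  term_table <- demo_term_table()
  drug_table <- default_drug_table()
  ra_drugs <- unique(drug_table$generic[drug_table$disease == "RA"])
  as_drugs <- unique(drug_table$generic[drug_table$disease == "AS"])

  ra_pairs <- filter(design, .data$stratum %in% c("RA", "both"))
  as_pairs <- filter(design, .data$stratum %in% c("AS", "both"))
  ra <- demo_stratum_registry("RA", ra_drugs, ra_pairs)
  as_ <- demo_stratum_registry("AS", as_drugs, as_pairs)
  reports <- bind_rows(ra$reports, as_$reports) |>
    left_join(term_table, by = c(term = "preferred_term")) |>
    mutate(report_id = sprintf("DR%06d", row_number()),
           severity = "I", outcome = "resolved") |>
    select("report_id", "event_id", "raw_term", "relatedness",
           "severity", "outcome", is_lab_abnormality = "is_lab")
  registry <- structure(
    list(patients = bind_rows(ra$patients, as_$patients),
         events = bind_rows(ra$events, as_$events),
         adr_reports = reports),
    class = "pv_registry"
  )

  srs <- demo_srs(design, term_table)
  mappings <- list(
    brand_map = distinct(drug_table, .data$brand, .data$generic),
    term_map = term_table
  )
  label_kb <- design |>
    filter(.data$role == "label_known") |>
    distinct(.data$drug, .data$term) |>
    mutate(provenance = "demo label knowledge base")

  catalog <- default_lab_catalog()
  lab_truth <- tibble(
    drug = c("tocilizumab", "tofacitinib"),
    signal_id = c("SIG039", "SIG002"),
    excursion_prob = c(0.35, 0.35)
  )
  lab_term_map <- tibble(
    signal_id = c("SIG039", "SIG002"),
    term = c("Haemoglobin decreased", "Blood fibrinogen increased")
  )
  truth <- ground_truth(
    registry_signals = design |>
      tidyr::uncount(weights = if_else(.data$stratum == "both", 2L, 1L),
                     .id = "copy") |>
      mutate(disease = if_else(.data$stratum == "both",
                               c("RA", "AS")[.data$copy], .data$stratum),
             rr = if_else(.data$disease == "RA", 21, 12)) |>
      select("disease", "drug", "term", "rr"),
    srs_signals = design |>
      filter(.data$role == "confirmed") |>
      distinct(.data$drug, .data$term) |>
      mutate(rrr = 10),
    lab_signals = lab_truth,
    label_known = label_kb |> select("drug", "term")
  )
  ehr <- generate_ehr_lab(
    ehr_config(n_patients = c(RA = 1411L, AS = 656L),
               drug_codes = unique(drug_table$generic),
               catalog = catalog$catalog,
               reference_ranges = catalog$reference_ranges,
               background_abnormal_prob = 0.02),
    truth = truth, seed = seed
  )
  list(registry = registry, srs = srs, ehr = ehr, mappings = mappings,
       label_kb = label_kb, catalog = catalog$catalog,
       lab_term_map = lab_term_map, truth = truth, design = design)
}

# Deterministic demo SRS: background reports give every term an identical
# reporting rate under two background drugs; confirmed pairs get 40 reports
# each (observed far above expected), unconfirmed candidates get 2 (below
# their expected count, so every statistic points the wrong way for them);
# three unconfirmed candidates are left out entirely to exercise the
# absent-from-SRS annotation.
demo_srs <- function(design, term_table) {
  all_terms <- term_table$preferred_term
  biologics <- unique(design$drug)
  confirmed <- filter(design, .data$role == "confirmed") |>
    distinct(.data$drug, .data$term)
  unconfirmed <- filter(design, .data$role == "unconfirmed") |>
    distinct(.data$drug, .data$term)
  absent <- unconfirmed[1:3, ]
  unconfirmed <- unconfirmed[-(1:3), ]

  background <- tidyr::expand_grid(
    drug_name = c("methotrexate", "prednisolone"),
    event_term = all_terms,
    rep = 1:100
  )
  padding <- tidyr::expand_grid(drug_name = biologics,
                                event_term = "Seasonal allergy",
                                rep = 1:300)
  conf_rows <- tidyr::expand_grid(
    k = seq_len(nrow(confirmed)), rep = 1:40
  ) |>
    mutate(drug_name = confirmed$drug[.data$k],
           event_term = confirmed$term[.data$k],
           # a quarter of confirmed-pair mentions arrive under a brand name
           drug_name = if_else(.data$rep <= 10L,
                               paste0(.data$drug_name, "-orig"),
                               .data$drug_name)) |>
    select("drug_name", "event_term")
  unconf_rows <- tidyr::expand_grid(
    k = seq_len(nrow(unconfirmed)), rep = 1:2
  ) |>
    mutate(drug_name = unconfirmed$drug[.data$k],
           event_term = unconfirmed$term[.data$k]) |>
    select("drug_name", "event_term")
  rows <- bind_rows(
    select(background, "drug_name", "event_term"),
    select(padding, "drug_name", "event_term"),
    conf_rows, unconf_rows
  ) |>
    mutate(report_id = sprintf("DS%06d", row_number())) |>
    select("report_id", "drug_name", "event_term")
  structure(rows, class = c("pv_srs", class(rows)),
            absent_candidates = absent)
}
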