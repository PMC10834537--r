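#' Select valid registry cases
#'
#' Applies the registry case-selection rules: keep one case per follow-up
#' event with drug status "continued" belonging to a non-withdrawn patient
#' (each follow-up event is an independent case); keep only ADR reports with
#' relatedness "related" or "indeterminate"; normalise brand names to
#' generics and raw terms to preferred terms.  Severity and outcome are
#' ignored.  Any brand name or raw term missing from the mapping tables is a
#' hard error listing the offending values — no silent drops.
#'
#' @param registry A `pv_registry` (see [generate_registry()]) or a list
#'   with tibbles `patients`, `events`, `adr_reports` in the same schema.
#' @param mappings List with `brand_map` (brand, generic) and `term_map`
#'   (raw_term, preferred_term, is_lab), as from
#'   [generate_mappings_and_labels()].
#' @return A tibble of cases, one row per kept follow-up event, with columns
#'   `case_id`, `disease`, `drug` (generic) and list-column `terms`
#'   (distinct preferred terms from related/indeterminate reports).  The
#'   character vector of lab-abnormality preferred terms is attached as
#'   attribute `"lab_terms"`.
#' @export
select_valid_cases <- function(registry, mappings) {
  ev <- registry$events
  kept_patients <- filter(registry$patients, !.data$withdrawal_flag)
  cases <- ev |>
    filter(.data$phase == "follow_up",
           .data$drug_status == "continued") |>
    semi_join(kept_patients, by = "patient_id")
  unmapped_brand <- setdiff(cases$drug_brand_name, mappings$brand_map$brand)
  if (length(unmapped_brand)) abort_unmapped("brand name", unmapped_brand)
  cases <- left_join(cases, mappings$brand_map,
                     by = c(drug_brand_name = "brand"))

  reports <- registry$adr_reports |>
    semi_join(cases, by = "event_id") |>
    filter(.data$relatedness %in% c("related", "indeterminate"))
  unmapped_term <- setdiff(reports$raw_term, mappings$term_map$raw_term)
  if (length(unmapped_term)) abort_unmapped("raw ADR term", unmapped_term)
  reports <- left_join(reports,
                       select(mappings$term_map, "raw_term", "preferred_term"),
                       by = "raw_term") |>
    distinct(.data$event_id, .data$preferred_term)

  term_sets <- split(reports$preferred_term,
                     factor(reports$event_id, levels = cases$event_id))
  out <- tibble(
    case_id = cases$event_id,
    disease = cases$disease,
    drug = cases$generic,
    terms = unname(term_sets)
  )
  attr(out, "lab_terms") <-
    sort(unique(mappings$term_map$preferred_term[mappings$term_map$is_lab]))
  out
}

# Vectorised pair counting over one disease stratum: every (drug, term)
# co-occurrence with its a, b, c, d cells.
stratum_pair_tables <- function(cases) {
  n_total <- nrow(cases)
  long <- tibble(
    drug = rep(cases$drug, lengths(cases$terms)),
    term = unlist(cases$terms, use.names = FALSE)
  )
  drug_n <- count(tibble(drug = cases$drug), .data$drug, name = "n_drug")
  term_n <- count(long, .data$term, name = "n_term")
  pair_a <- count(long, .data$drug, .data$term, name = "a")
  pair_a |>
    left_join(drug_n, by = "drug") |>
    left_join(term_n, by = "term") |>
    mutate(
      b = .data$n_drug - .data$a,
      c = .data$n_term - .data$a,
      d = n_total - .data$n_drug - .data$n_term + .data$a
    ) |>
    select("drug", "term", "a", "b", "c", "d")
}

#' Screen registry cases for significant drug-ADR pairs
#'
#' Builds per-disease 2x2 tables for every observed (drug, term) pair with
#' at least `min_count` co-occurrences and computes the relative risk with a
#' Katz confidence interval.  By default a pair is significant when `rr > 1`
#' and the unrounded CI lower bound exceeds 1; `point_estimate_only = TRUE`
#' reproduces the literal `rr > 1` rule.
#'
#' @param cases Case tibble from [select_valid_cases()].
#' @param alpha CI level (default 0.05 for 95% intervals).
#' @param min_count Minimum co-occurrence count `a` for a pair to be
#'   evaluated (default 3).
#' @param point_estimate_only If TRUE, significance is `rr > 1` alone.
#' @param lab_terms Character vector of preferred terms that are laboratory
#'   abnormalities; defaults to the `"lab_terms"` attribute on `cases`.
#' @return A `pv_signal` tibble with columns `disease`, `drug`, `term`, `a`,
#'   `rr`, `ci_low`, `ci_high`, `significant`, `is_lab_abnormality`, one row
#'   per evaluated pair, per disease stratum.
#' @export
screen_registry <- function(cases, alpha = 0.05, min_count = 3L,
                            point_estimate_only = FALSE,
                            lab_terms = attr(cases, "lab_terms")) {
  if (nrow(cases) == 0L) abort("no cases to screen")
  lab_terms <- lab_terms %||% character()
  res <- cases |>
    dplyr::group_split(.data$disease) |>
    purrr::map(function(str_cases) {
      dis <- str_cases$disease[[1]]
      tabs <- stratum_pair_tables(str_cases) |>
        filter(.data$a >= min_count)
      if (nrow(tabs) == 0L) return(NULL)
      est <- relative_risk(tabs$a, tabs$b, tabs$c, tabs$d, alpha = alpha)
      sig <- if (point_estimate_only) {
        !is.na(est$rr) & est$rr > 1
      } else {
        !is.na(est$rr) & !is.na(est$ci_low) & est$rr > 1 & est$ci_low > 1
      }
      tibble(
        disease = dis, drug = tabs$drug, term = tabs$term, a = tabs$a,
        rr = est$rr, ci_low = est$ci_low, ci_high = est$ci_high,
        significant = sig,
        is_lab_abnormality = tabs$term %in% lab_terms
      )
    }) |>
    bind_rows() |>
    arrange(.data$disease, dplyr::desc(.data$significant), .data$drug,
            .data$term)
  structure(res, class = c("pv_signal", class(res)))
}
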