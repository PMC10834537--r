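direction_predicate <- function(direction, value, lower, upper) {
  switch(direction,
    above_upper = value > upper,
    below_lower = value < lower,
    outside_range = value > upper | value < lower,
    abort(paste0("unknown laboratory signal direction: ", direction))
  )
}

#' Classify one patient against one laboratory-signal definition
#'
#' TRUE iff at least one measurement of the signal's test, dated within the
#' window after the patient's first exposure start, satisfies the direction
#' predicate (strictly above the upper limit, strictly below the lower
#' limit, or strictly outside the range — a value equal to a limit is
#' normal).  For unexposed patients pass `exposure_start = NULL`: the
#' window is their whole observation span.
#'
#' @param measurements Tibble with columns `test_id`, `value`, `date` for
#'   one patient.
#' @param definition One-row tibble (or list) with `test_id`, `direction`.
#' @param reference_ranges Tibble `test_id`, `lower_limit`, `upper_limit`.
#' @param exposure_start Date of first exposure, or NULL if unexposed.
#' @param window_days Length of the post-exposure window in days.
#' @return Logical scalar.
#' @export
classify_patient_signal <- function(measurements, definition,
                                    reference_ranges,
                                    exposure_start = NULL,
                                    window_days = 365L) {
  m <- filter(measurements, .data$test_id == definition$test_id)
  if (nrow(m) == 0L) return(FALSE)
  rng <- filter(reference_ranges, .data$test_id == definition$test_id)
  if (nrow(rng) == 0L) {
    abort(paste0("no reference range for test ", definition$test_id))
  }
  if (!is.null(exposure_start)) {
    m <- filter(m, .data$date >= exposure_start,
                .data$date <= exposure_start + window_days)
    if (nrow(m) == 0L) return(FALSE)
  }
  any(direction_predicate(definition$direction, m$value,
                          rng$lower_limit, rng$upper_limit))
}

#' Laboratory-abnormality signal screen on EHR-style data
#'
#' For every (drug, lab-signal) pair, classifies each eligible patient by
#' drug exposure and by occurrence of the signal, builds the patient-level
#' 2x2 table (a = exposed with signal, b = exposed without, c = comparator
#' with signal, d = comparator without), and computes the relative risk via
#' [relative_risk()] with a two-sided p-value (Pearson chi-square, or
#' Fisher's exact test when any expected cell is below 5).  A pair is
#' significant when `rr > 1` and `p < 0.05`.  The comparator group is
#' patients on the other catalog drugs (`comparator = "other_drugs"`, the
#' default) or all other patients.
#'
#' Pairs with no exposed or no comparator patient are skipped with a log
#' note.
#'
#' @param ehr A `pv_ehr` (see [generate_ehr_lab()]) or list with tibbles
#'   `exposures`, `measurements`, `reference_ranges` in the same schema.
#' @param catalog Tibble `signal_id`, `test_id`, `direction`.
#' @param disease_codes Optional character vector restricting patients by
#'   `disease_code`.
#' @param drug_codes Drug codes to screen; defaults to all codes present.
#' @param window_days Post-exposure window (days).
#' @param comparator `"other_drugs"` or `"all_patients"`.
#' @param alpha CI level for the relative risk.
#' @return A `pv_lab_signal` tibble: `disease_code` (collapsed label),
#'   `drug`, `signal_id`, `test_id`, `direction`, `a`, `b`, `c`, `d`, `rr`,
#'   `ci_low`, `ci_high`, `p_value`, `significant`.
#' @export
screen_lab <- function(ehr, catalog, disease_codes = NULL,
                       drug_codes = NULL, window_days = 365L,
                       comparator = c("other_drugs", "all_patients"),
                       alpha = 0.05) {
  comparator <- match.arg(comparator)
  if (nrow(catalog) == 0L) abort("laboratory catalog must be non-empty")
  expo <- ehr$exposures
  if (!is.null(disease_codes)) {
    expo <- filter(expo, .data$disease_code %in% disease_codes)
  }
  drug_codes <- drug_codes %||% sort(unique(expo$drug_code))
  missing_rng <- setdiff(unique(ehr$measurements$test_id),
                         ehr$reference_ranges$test_id)
  if (length(missing_rng)) abort_unmapped("test reference range", missing_rng)

  meas <- ehr$measurements |>
    semi_join(expo, by = "patient_id") |>
    left_join(select(expo, "patient_id", "start_date"), by = "patient_id") |>
    left_join(ehr$reference_ranges, by = "test_id") |>
    filter(.data$date >= .data$start_date,
           .data$date <= .data$start_date + window_days)

  # per (patient, signal): any in-window measurement meeting the predicate
  signal_hits <- purrr::map(seq_len(nrow(catalog)), function(i) {
    m <- filter(meas, .data$test_id == catalog$test_id[i])
    hit <- direction_predicate(catalog$direction[i], m$value,
                               m$lower_limit, m$upper_limit)
    tibble(signal_id = catalog$signal_id[i],
           patient_id = unique(m$patient_id[hit]))
  }) |> bind_rows()

  dis_label <- paste(sort(unique(expo$disease_code)), collapse = "+")
  res <- purrr::map(drug_codes, function(dr) {
    exposed <- expo$patient_id[expo$drug_code == dr]
    comp <- if (comparator == "other_drugs") {
      expo$patient_id[expo$drug_code != dr & expo$drug_code %in% drug_codes]
    } else {
      expo$patient_id[expo$drug_code != dr]
    }
    if (length(exposed) == 0L || length(comp) == 0L) {
      inform(paste0("skipping drug ", dr,
                    ": no exposed or no comparator patients"))
      return(NULL)
    }
    purrr::map(unique(catalog$signal_id), function(sid) {
      with_sig <- signal_hits$patient_id[signal_hits$signal_id == sid]
      a <- sum(exposed %in% with_sig)
      b <- length(exposed) - a
      c <- sum(comp %in% with_sig)
      d <- length(comp) - c
      est <- relative_risk(a, b, c, d, alpha = alpha)
      p <- lab_pair_pvalue(a, b, c, d)
      def <- catalog[catalog$signal_id == sid, ][1, ]
      tibble(disease_code = dis_label, drug = dr, signal_id = sid,
             test_id = def$test_id, direction = def$direction,
             a = a, b = b, c = c, d = d,
             rr = est$rr, ci_low = est$ci_low, ci_high = est$ci_high,
             p_value = p,
             significant = !is.na(est$rr) & est$rr > 1 &
               !is.na(p) & p < 0.05)
    }) |> bind_rows()
  }) |> bind_rows()
  structure(res, class = c("pv_lab_signal", class(res)))
}

# Two-sided p-value for a patient-level 2x2: Pearson chi-square, switching
# to Fisher's exact test when any expected cell is below 5.
lab_pair_pvalue <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(m)
  if (n == 0) return(NA_real_)
  expected <- outer(rowSums(m), colSums(m)) / n
  if (any(expected < 5)) {
    fisher.test(m)$p.value
  } else {
    suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
  }
}
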