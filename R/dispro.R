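#' Build the case/non-case report table from spontaneous reports
#'
#' The counting unit is the distinct report.  For each (drug, event) pair:
#' `a` = reports mentioning both, `b` = reports with the drug and other
#' events, `c` = reports with the event and other drugs, `d` = the
#' remainder.  A report carrying k drugs and m events contributes to all
#' k x m pairs; duplicate (report, drug, event) rows are collapsed first.
#' Brand names are normalised to generics through the mapping table.
#'
#' @param srs Tibble with columns `report_id`, `drug_name`, `event_term`.
#' @param mappings List with `brand_map` (brand, generic) and optionally
#'   `term_map` (raw_term, preferred_term) applied to event terms.
#' @param drug_universe Optional character vector of valid generic drug
#'   names; when supplied, any drug name that is neither a mapped brand nor
#'   in this universe raises a hard error (unmapped brand).  When NULL,
#'   unmapped names are assumed to already be generic.
#' @return A `pv_report_table` tibble with columns `drug`, `event`, `a`,
#'   `b`, `c`, `d`; the distinct report count is attached as attribute
#'   `"n_reports"`.
#' @export
build_case_noncase <- function(srs, mappings, drug_universe = NULL) {
  bm <- mappings$brand_map
  lookup <- setNames(bm$generic, bm$brand)
  mapped <- lookup[srs$drug_name]
  drug <- ifelse(is.na(mapped), srs$drug_name, mapped)
  if (!is.null(drug_universe)) {
    bad <- setdiff(unique(drug), drug_universe)
    if (length(bad)) abort_unmapped("SRS drug name", bad)
  }
  event <- srs$event_term
  if (!is.null(mappings$term_map)) {
    tm <- mappings$term_map
    ev_mapped <- setNames(tm$preferred_term, tm$raw_term)[event]
    event <- ifelse(is.na(ev_mapped), event, ev_mapped)
  }
  mentions <- distinct(tibble(report_id = srs$report_id,
                              drug = drug, event = event))
  n_reports <- dplyr::n_distinct(mentions$report_id)
  drug_reports <- distinct(mentions, .data$report_id, .data$drug) |>
    count(.data$drug, name = "n_drug")
  event_reports <- distinct(mentions, .data$report_id, .data$event) |>
    count(.data$event, name = "n_event")
  pairs <- count(mentions, .data$drug, .data$event, name = "a") |>
    left_join(drug_reports, by = "drug") |>
    left_join(event_reports, by = "event") |>
    mutate(
      b = .data$n_drug - .data$a,
      c = .data$n_event - .data$a,
      d = n_reports - .data$n_drug - .data$n_event + .data$a
    ) |>
    select("drug", "event", "a", "b", "c", "d")
  structure(pairs, n_reports = n_reports,
            class = c("pv_report_table", class(pairs)))
}

#' Disproportionality statistics for 2x2 case/non-case cells
#'
#' Computes the proportional reporting ratio
#' `PRR = (a/(a+b)) / (c/(c+d))`, the reporting odds ratio
#' `ROR = (a/b) / (c/d)`, and the information component
#' `IC = log2( a * n / ((a+c) * (a+b)) )` with `n = a+b+c+d`.  When any
#' cell is zero, 0.5 is added to all four cells (Haldane-Anscombe
#' continuity correction) for the point estimates and variances, and the
#' result is flagged `corrected`.
#'
#' All arguments are vectorised.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @return Tibble with columns `prr`, `ror`, `ic`, `corrected`.
#' @examples
#' dispro_stats(2, 2, 1, 3) # prr = 2, ror = 3, ic = log2(16/12)
#' @export
dispro_stats <- function(a, b, c, d) {
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    abort("cell counts must be non-negative")
  }
  if (any(a + b + c + d == 0)) abort("all-zero contingency table")
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  cc <- ifelse(corrected, 0.5, 0)
  a2 <- a + cc; b2 <- b + cc; c2 <- c + cc; d2 <- d + cc
  n2 <- a2 + b2 + c2 + d2
  tibble(
    prr = (a2 / (a2 + b2)) / (c2 / (c2 + d2)),
    ror = (a2 / b2) / (c2 / d2),
    ic = log2(a2 * n2 / ((a2 + c2) * (a2 + b2))),
    corrected = corrected
  )
}

# Posterior probability P(IC <= 0 | data) under independent
# Dirichlet-multinomial (Beta) posteriors for the joint cell and the two
# margins: p11 ~ Beta(a+1, n-a+1), p_drug ~ Beta(a+b+1, c+d+1),
# p_event ~ Beta(a+c+1, b+d+1), IC = log2(p11 / (p_drug * p_event)).
# Seeded Monte Carlo, chunked to bound memory.
ic_posterior_null <- function(a, b, c, d, mc_draws = 10000L, seed = 1L) {
  set.seed(child_seed(seed, "fdr_ic"))
  n <- a + b + c + d
  n_pairs <- length(a)
  out <- numeric(n_pairs)
  block <- max(1L, floor(2e6 / mc_draws))
  for (start in seq(1L, n_pairs, by = block)) {
    idx <- start:min(start + block - 1L, n_pairs)
    k <- length(idx)
    p11 <- matrix(rbeta(k * mc_draws, rep(a[idx] + 1, mc_draws),
                        rep(n[idx] - a[idx] + 1, mc_draws)), nrow = k)
    prow <- matrix(rbeta(k * mc_draws, rep(a[idx] + b[idx] + 1, mc_draws),
                         rep(c[idx] + d[idx] + 1, mc_draws)), nrow = k)
    pcol <- matrix(rbeta(k * mc_draws, rep(a[idx] + c[idx] + 1, mc_draws),
                         rep(b[idx] + d[idx] + 1, mc_draws)), nrow = k)
    # IC <= 0  <=>  p11 <= prow * pcol
    out[idx] <- rowMeans(p11 <= prow * pcol)
  }
  out
}

#' FDR-ranked decisions for disproportionality statistics
#'
#' For PRR and ROR: a one-sided p-value from the Wald statistic on the log
#' scale (`se_logPRR = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`,
#' `se_logROR = sqrt(1/a + 1/b + 1/c + 1/d)`; continuity-corrected cells
#' are used when any cell is zero), adjusted by Benjamini-Hochberg.  For
#' the information component: the Monte-Carlo posterior probability
#' `P(IC <= 0 | data)` under a Dirichlet posterior over the 2x2 cells; the
#' FDR at rank i is the cumulative mean of the posterior null
#' probabilities sorted in increasing order (so the FDR sequence is
#' non-decreasing in rank).
#'
#' @param tab A `pv_report_table` (or tibble with columns `a`,`b`,`c`,`d`).
#' @param method One of `"prr"`, `"ror"`, `"ic"`.
#' @param mc_draws Monte-Carlo draws for the IC posterior (a value below
#'   1000 is accepted with a warning).
#' @param seed Seed for the IC Monte Carlo.
#' @return Numeric vector of FDR values aligned with the rows of `tab`.
#' @export
fdr_rank <- function(tab, method = c("prr", "ror", "ic"),
                     mc_draws = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (nrow(tab) < 1L) abort("at least one pair is required")
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  if (method == "ic") {
    if (mc_draws < 1000L) {
      warn("mc_draws < 1000: IC posterior estimates will be noisy")
    }
    post_null <- ic_posterior_null(a, b, c, d, mc_draws = mc_draws,
                                   seed = seed)
    return(fdr_from_posterior(post_null))
  }
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  cc <- ifelse(corrected, 0.5, 0)
  a2 <- a + cc; b2 <- b + cc; c2 <- c + cc; d2 <- d + cc
  if (method == "prr") {
    est <- (a2 / (a2 + b2)) / (c2 / (c2 + d2))
    se <- sqrt(1 / a2 - 1 / (a2 + b2) + 1 / c2 - 1 / (c2 + d2))
  } else {
    est <- (a2 / b2) / (c2 / d2)
    se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  }
  z <- log(est) / se
  p <- pnorm(z, lower.tail = FALSE)
  p.adjust(p, method = "BH")
}

# Bayesian FDR from posterior null probabilities: the FDR at rank i is the
# cumulative mean of the sorted posterior null probabilities, which is
# non-decreasing in rank.
fdr_from_posterior <- function(post_null) {
  ord <- order(post_null)
  fdr <- numeric(length(ord))
  fdr[ord] <- cumsum(post_null[ord]) / seq_along(ord)
  fdr
}

#' Full disproportionality screen of a report table
#'
#' Computes PRR, ROR and IC with their FDR-ranked decisions and the
#' any-of-the-three significance flag at the given FDR threshold.
#'
#' @param tab A `pv_report_table` from [build_case_noncase()].
#' @param threshold FDR significance threshold (default 0.05).
#' @param mc_draws,seed Passed to [fdr_rank()] for the IC posterior.
#' @return A `pv_dispro` tibble: `drug`, `event`, `a`, `prr`, `ror`, `ic`,
#'   `corrected`, `fdr_prr`, `fdr_ror`, `fdr_ic`, `significant_any`.
#' @export
dispro_screen <- function(tab, threshold = 0.05, mc_draws = 10000L,
                          seed = 1L) {
  if (nrow(tab) == 0L) {
    empty <- tibble(
      drug = character(), event = character(), a = integer(),
      prr = numeric(), ror = numeric(), ic = numeric(),
      corrected = logical(), fdr_prr = numeric(), fdr_ror = numeric(),
      fdr_ic = numeric(), significant_any = logical()
    )
    return(structure(empty, threshold = threshold,
                     class = c("pv_dispro", class(empty))))
  }
  stats <- dispro_stats(tab$a, tab$b, tab$c, tab$d)
  res <- tibble(
    drug = tab$drug, event = tab$event, a = tab$a,
    prr = stats$prr, ror = stats$ror, ic = stats$ic,
    corrected = stats$corrected,
    fdr_prr = fdr_rank(tab, "prr"),
    fdr_ror = fdr_rank(tab, "ror"),
    fdr_ic = fdr_rank(tab, "ic", mc_draws = mc_draws, seed = seed)
  ) |>
    mutate(significant_any =
             pmin(.data$fdr_prr, .data$fdr_ror, .data$fdr_ic) < threshold)
  structure(res, threshold = threshold,
            class = c("pv_dispro", class(res)))
}

#' Annotate novel candidates with spontaneous-report evidence
#'
#' Looks each candidate (drug, term) pair up in the disproportionality
#' results.  A pair that never co-occurs in the SRS is annotated as absent
#' (`in_srs = FALSE`) and not significant, mirroring NA rows in published
#' signal tables.
#'
#' @param candidates Tibble of novel pairs with columns `drug`, `term`.
#' @param dispro A `pv_dispro` tibble from [dispro_screen()].
#' @param threshold FDR threshold used for `significant_any` (defaults to
#'   the threshold stored on `dispro`).
#' @return The candidates with annotation columns `in_srs`, `srs_a`, `prr`,
#'   `ror`, `ic`, `fdr_prr`, `fdr_ror`, `fdr_ic`, `significant_any`.
#' @export
validate_candidates <- function(candidates, dispro, threshold = NULL) {
  threshold <- threshold %||% attr(dispro, "threshold") %||% 0.05
  ann <- dispro |>
    as_tibble() |>
    select("drug", term = "event", srs_a = "a", "prr", "ror", "ic",
           "fdr_prr", "fdr_ror", "fdr_ic") |>
    mutate(in_srs = TRUE)
  out <- candidates |>
    as_tibble() |>
    left_join(ann, by = c("drug", "term")) |>
    mutate(
      in_srs = !is.na(.data$in_srs),
      significant_any = .data$in_srs &
        pmin(.data$fdr_prr, .data$fdr_ror, .data$fdr_ic) < threshold
    )
  out$significant_any[is.na(out$significant_any)] <- FALSE
  out
}
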