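#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_hline geom_vline scale_x_log10 labs facet_wrap theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a pipeline run into the final signal table
#'
#' @param x A `pv_run` from [run_pipeline()].
#' @param ... Unused.
#' @return The final signal tibble (one row per final drug-ADR pair).
#' @export
tidy.pv_run <- function(x, ...) {
  as_tibble(x$final)
}

#' One-row flow summary of a pipeline run
#'
#' The analogue of a flow diagram: case counts, significant, novel and
#' excluded pairs per stratum, SRS-confirmed candidates, and final signals.
#'
#' @param x A `pv_run` from [run_pipeline()].
#' @param ... Unused.
#' @export
glance.pv_run <- function(x, ...) {
  ct <- x$counts
  grab <- function(tb, k) if (k %in% names(tb)) as.integer(tb[[k]]) else 0L
  tibble(
    n_cases_RA = grab(ct$n_cases, "RA"),
    n_cases_AS = grab(ct$n_cases, "AS"),
    n_significant_RA = grab(ct$n_significant, "RA"),
    n_significant_AS = grab(ct$n_significant, "AS"),
    n_novel_RA = grab(ct$n_novel, "RA"),
    n_novel_AS = grab(ct$n_novel, "AS"),
    n_candidates = ct$n_candidates,
    n_srs_confirmed = ct$n_srs_confirmed,
    n_final = ct$n_final
  )
}

#' @export
print.pv_run <- function(x, ...) {
  cat("<pvscreen pipeline run>\n")
  cat("  output: ", x$out_dir, " (seed ", x$seed, ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Forest plot of registry signal relative risks
#'
#' Significant pairs with their Katz confidence intervals, faceted by
#' disease stratum.
#'
#' @param object A `pv_signal` tibble from [screen_registry()].
#' @param max_pairs Plot at most this many pairs per stratum (largest RR
#'   first).
#' @param ... Unused.
#' @export
autoplot.pv_signal <- function(object, max_pairs = 30L, ...) {
  df <- object |>
    filter(.data$significant, is.finite(.data$rr)) |>
    group_by(.data$disease) |>
    arrange(dplyr::desc(.data$rr)) |>
    dplyr::slice_head(n = max_pairs) |>
    ungroup() |>
    mutate(pair = paste(.data$drug, .data$term, sep = " — "))
  ggplot(df, aes(x = .data$rr, y = stats::reorder(.data$pair, .data$rr))) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    scale_x_log10() +
    facet_wrap(~disease, scales = "free_y") +
    labs(x = "relative risk (log scale)", y = NULL,
         title = "Registry drug–ADR signals") +
    theme_minimal()
}

#' Disproportionality overview plot
#'
#' Information component against the proportional reporting ratio for every
#' drug-event pair, marking pairs significant at the FDR threshold on any
#' statistic.
#'
#' @param object A `pv_dispro` tibble from [dispro_screen()].
#' @param ... Unused.
#' @export
autoplot.pv_dispro <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$prr, y = .data$ic,
             colour = .data$significant_any)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    geom_vline(xintercept = 1, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "PRR (log scale)", y = "information component (IC)",
         colour = "FDR-significant",
         title = "Spontaneous-report disproportionality") +
    theme_minimal()
}

#' Laboratory screen plot
#'
#' Relative risks of significant (drug, laboratory-signal) pairs.
#'
#' @param object A `pv_lab_signal` tibble from [screen_lab()].
#' @param ... Unused.
#' @export
autoplot.pv_lab_signal <- function(object, ...) {
  df <- filter(as_tibble(object), .data$significant) |>
    mutate(pair = paste(.data$drug, .data$signal_id, sep = " — "))
  ggplot(df, aes(x = .data$rr, y = stats::reorder(.data$pair, .data$rr))) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_vline(xintercept = 1, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "relative risk (log scale)", y = NULL,
         title = "Drug–laboratory abnormality signals") +
    theme_minimal()
}
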