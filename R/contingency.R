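#' Build a 2x2 contingency table for one drug-event pair
#'
#' Cell semantics are shared by every screen in the package: `a` = cases on
#' the drug of interest with the event of interest, `b` = cases on the drug
#' without it, `c` = cases on other drugs with the event, `d` = the
#' remainder.  The counting unit depends on the caller (registry follow-up
#' case, distinct spontaneous report, or patient).
#'
#' @param cases A tibble of registry cases as returned by
#'   [select_valid_cases()]: one row per case with columns `case_id`,
#'   `disease`, `drug` and a list-column `terms` of preferred terms.  All
#'   cases must come from a single disease stratum.
#' @param drug Generic drug name of interest.
#' @param term Preferred term of interest.
#' @return A one-row tibble with integer columns `a`, `b`, `c`, `d` and the
#'   derived total `n`.
#' @examples
#' cases <- tibble::tibble(
#'   case_id = 1:4, disease = "RA",
#'   drug = c("drugX", "drugX", "drugY", "drugY"),
#'   terms = list("t", character(), "t", character())
#' )
#' build_contingency(cases, "drugX", "t")
#' @export
build_contingency <- function(cases, drug, term) {
  if (nrow(cases) == 0L) {
    abort("cannot build a contingency table from an empty case list")
  }
  if (length(unique(cases$disease)) > 1L) {
    abort("cases must come from a single disease stratum")
  }
  on_drug <- cases$drug == drug
  has_term <- map_lgl(cases$terms, function(ts) term %in% ts)
  a <- sum(on_drug & has_term)
  b <- sum(on_drug & !has_term)
  c <- sum(!on_drug & has_term)
  d <- sum(!on_drug & !has_term)
  tibble(a = a, b = b, c = c, d = d, n = a + b + c + d)
}

#' Relative risk with a Katz log-normal confidence interval
#'
#' Computes `rr = (a/(a+b)) / (c/(c+d))` with the Katz (log-RR Wald)
#' interval `exp(log(rr) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#' No continuity correction is applied: when `a = 0` and `c > 0` the point
#' estimate is 0 with an undefined (NA) interval; when `c = 0` both the
#' estimate and the interval are reported as NA.
#'
#' All arguments are vectorised.
#'
#' @param a,b,c,d Non-negative integer cell counts (see
#'   [build_contingency()] for semantics).
#' @param alpha Two-sided type-I error for the interval (default 0.05 for a
#'   95% CI).
#' @return A tibble with columns `rr`, `ci_low`, `ci_high`.
#' @examples
#' relative_risk(10, 90, 10, 190) # rr = 2
#' @export
relative_risk <- function(a, b, c, d, alpha = 0.05) {
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    abort("cell counts must be non-negative")
  }
  if (any(a + b == 0) || any(c + d == 0)) {
    abort("relative risk requires a+b > 0 and c+d > 0")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  rr <- (a / (a + b)) / (c / (c + d))
  rr[c == 0] <- NA_real_
  rr[a == 0 & c > 0] <- 0
  z <- qnorm(1 - alpha / 2)
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  lo <- exp(log(rr) - z * se)
  hi <- exp(log(rr) + z * se)
  undef <- a == 0 | c == 0
  lo[undef] <- NA_real_
  hi[undef] <- NA_real_
  tibble(rr = rr, ci_low = lo, ci_high = hi)
}
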