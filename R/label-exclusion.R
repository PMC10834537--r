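#' Partition significant signals into novel and label-known
#'
#' Removes drug-ADR pairs already documented in the label knowledge base,
#' yielding the novel candidates that go forward to external validation.
#' Matching is on exact normalised (drug, term) pairs and is
#' disease-agnostic: a label-known pair is excluded in every stratum.  Only
#' significant input rows are partitioned; both partitions preserve input
#' order.
#'
#' @param signals A signal tibble from [screen_registry()] (columns `drug`,
#'   `term`, `significant`, ...).
#' @param kb Label knowledge base: tibble with columns `drug`, `term` (and
#'   optionally `provenance`).
#' @return List with tibbles `novel` and `excluded`, a partition of the
#'   significant rows of `signals`.
#' @export
filter_novel <- function(signals, kb) {
  sig <- filter(signals, .data$significant)
  known <- distinct(kb, .data$drug, .data$term)
  is_known <- paste0(sig$drug, "\r", sig$term) %in%
    paste0(known$drug, "\r", known$term)
  list(
    novel = sig[!is_known, , drop = FALSE],
    excluded = sig[is_known, , drop = FALSE]
  )
}
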