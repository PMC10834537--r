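#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct n bind_rows across
#'   count rename relocate pull if_else row_number
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_dbl map_lgl map_int walk
#' @importFrom stats pnorm qnorm p.adjust rbinom rpois runif rgamma rbeta
#'   chisq.test fisher.test setNames
#' @importFrom utils head
NULL

# Derive a reproducible child seed for a named random stream from one master
# seed.  Keeps results < 2^31 so they remain valid R integer seeds.
child_seed <- function(seed, stream) {
  streams <- c(
    registry = 101L, srs = 211L, ehr = 307L, mappings = 401L,
    demo = 503L, fdr_ic = 601L
  )
  if (!stream %in% names(streams)) {
    abort(paste0("unknown random stream: ", stream))
  }
  (abs(as.integer(seed)) %% 1000000L) * 1009L + streams[[stream]]
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", name, "` must contain probabilities in [0, 1]"))
  }
  invisible(x)
}

# Stop with a message listing offending values; used wherever the contract
# forbids silent drops (unmapped brands / raw terms).
abort_unmapped <- function(kind, values) {
  values <- sort(unique(values))
  shown <- paste(head(values, 10L), collapse = ", ")
  more <- if (length(values) > 10L) paste0(" (and ", length(values) - 10L, " more)") else ""
  abort(paste0("unmapped ", kind, ": ", shown, more))
}

write_tsv_file <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

read_tsv_file <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types %||% readr::cols(),
                  progress = FALSE, show_col_types = FALSE)
}
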