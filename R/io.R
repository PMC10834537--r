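#' Write and read the package's delimited dataset schemas
#'
#' All datasets are exchanged as UTF-8 tab-separated files with a header
#' row.  The registry is three files (`patients.tsv`, `events.tsv`,
#' `adr_reports.tsv`), the EHR laboratory data three files
#' (`exposures.tsv`, `measurements.tsv`, `reference_ranges.tsv`), the SRS
#' one file, and the mapping tables / label knowledge base one file each.
#'
#' @param registry,srs,ehr,mappings,kb Objects in the schemas produced by
#'   the generators.
#' @param dir,path Target directory / file path.
#' @return The directory or path, invisibly.
#' @name pv_io
NULL

#' @rdname pv_io
#' @export
write_registry_data <- function(registry, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(registry$patients, file.path(dir, "patients.tsv"))
  write_tsv_file(registry$events, file.path(dir, "events.tsv"))
  write_tsv_file(registry$adr_reports, file.path(dir, "adr_reports.tsv"))
  invisible(dir)
}

#' @rdname pv_io
#' @export
read_registry_data <- function(dir) {
  structure(
    list(
      patients = read_tsv_file(file.path(dir, "patients.tsv")),
      events = read_tsv_file(file.path(dir, "events.tsv")),
      adr_reports = read_tsv_file(file.path(dir, "adr_reports.tsv"))
    ),
    class = "pv_registry"
  )
}

#' @rdname pv_io
#' @export
write_srs_data <- function(srs, path) {
  write_tsv_file(as_tibble(srs), path)
}

#' @rdname pv_io
#' @export
read_srs_data <- function(path) {
  x <- read_tsv_file(path, readr::cols(.default = readr::col_character()))
  structure(x, class = c("pv_srs", class(x)))
}

#' @rdname pv_io
#' @export
write_ehr_data <- function(ehr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(ehr$exposures, file.path(dir, "exposures.tsv"))
  write_tsv_file(ehr$measurements, file.path(dir, "measurements.tsv"))
  write_tsv_file(ehr$reference_ranges, file.path(dir, "reference_ranges.tsv"))
  invisible(dir)
}

#' @rdname pv_io
#' @export
read_ehr_data <- function(dir) {
  structure(
    list(
      exposures = read_tsv_file(file.path(dir, "exposures.tsv")),
      measurements = read_tsv_file(file.path(dir, "measurements.tsv")),
      reference_ranges = read_tsv_file(file.path(dir, "reference_ranges.tsv"))
    ),
    class = "pv_ehr"
  )
}

#' @rdname pv_io
#' @export
write_mappings <- function(mappings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(mappings$brand_map, file.path(dir, "brand_map.tsv"))
  write_tsv_file(mappings$term_map, file.path(dir, "term_map.tsv"))
  invisible(dir)
}

#' @rdname pv_io
#' @export
read_mappings <- function(dir) {
  list(
    brand_map = read_tsv_file(file.path(dir, "brand_map.tsv")),
    term_map = read_tsv_file(file.path(dir, "term_map.tsv"))
  )
}

#' @rdname pv_io
#' @export
write_label_kb <- function(kb, path) {
  if (!"provenance" %in% names(kb)) kb$provenance <- NA_character_
  write_tsv_file(distinct(kb, .data$drug, .data$term, .data$provenance), path)
}

#' @rdname pv_io
#' @export
read_label_kb <- function(path) {
  distinct(read_tsv_file(path))
}

#' Serialize ground truth as a structured sidecar file
#'
#' @param truth A [ground_truth()].
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(
    registry_signals = as_tibble(x$registry_signals),
    srs_signals = as_tibble(x$srs_signals),
    lab_signals = as_tibble(x$lab_signals),
    label_known = as_tibble(x$label_known)
  )
}
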