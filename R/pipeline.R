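#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [run_pipeline()].  `data` is either `list(demo = TRUE)` to generate the
#' shipped deterministic demonstration fixture, or a list of input paths:
#' `registry_dir` (patients/events/adr_reports TSVs), `srs_path`,
#' `mappings_dir` (brand_map/term_map TSVs), `kb_path`, and optionally
#' `ehr_dir`, `catalog_path`, `lab_term_map_path` for the laboratory
#' screen.
#'
#' @param data Input specification (see above).
#' @param alpha CI level for relative risks (default 0.05).
#' @param fdr_threshold FDR threshold for SRS significance (default 0.05).
#' @param min_count Minimum registry pair count (default 3).
#' @param point_estimate_only Use the literal RR > 1 registry rule.
#' @param mc_draws Monte-Carlo draws for the IC posterior.
#' @param window_days Laboratory screen exposure window.
#' @param run_metalab Whether to run the laboratory screen.
#' @param seed Master seed (can be overridden in [run_pipeline()]).
#' @return A `pv_config` list.
#' @export
pv_config <- function(data = list(demo = TRUE), alpha = 0.05,
                      fdr_threshold = 0.05, min_count = 3L,
                      point_estimate_only = FALSE, mc_draws = 10000L,
                      window_days = 365L, run_metalab = TRUE,
                      seed = 20240201L) {
  if (is.null(data$demo) || !isTRUE(data$demo)) {
    required <- c("registry_dir", "srs_path", "mappings_dir", "kb_path")
    missing <- setdiff(required, names(data))
    if (length(missing)) {
      abort(paste0("config error: data is missing ",
                   paste(missing, collapse = ", ")))
    }
  }
  if (fdr_threshold <= 0 || fdr_threshold >= 1) {
    abort("config error: fdr_threshold must lie in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) abort("config error: alpha must lie in (0, 1)")
  structure(
    list(data = data, alpha = alpha, fdr_threshold = fdr_threshold,
         min_count = as.integer(min_count),
         point_estimate_only = isTRUE(point_estimate_only),
         mc_draws = as.integer(mc_draws),
         window_days = as.integer(window_days),
         run_metalab = isTRUE(run_metalab), seed = as.integer(seed)),
    class = "pv_config"
  )
}

#' @rdname pv_config
#' @param path Path to a YAML configuration file with the same fields.
#' @export
read_pv_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pv_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("config error: unknown fields ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(pv_config, raw)
}

#' Intersect registry-novel candidates with SRS-significant pairs
#'
#' The final signal rule: a pair is a final candidate iff it is
#' registry-significant, label-novel, and significant on any of PRR, ROR or
#' IC in the spontaneous-report screen.  A pair significant in both disease
#' strata appears once, with both strata recorded and per-stratum registry
#' evidence in wide columns.
#'
#' @param novel Per-stratum novel signal tibble (from [filter_novel()],
#'   strata concatenated), columns `disease`, `drug`, `term`, `a`, `rr`,
#'   `ci_low`, `ci_high`, ...
#' @param annotated SRS-annotated candidates from [validate_candidates()].
#' @return A `pv_final` tibble, one row per final (drug, term) pair, with
#'   `diseases` (e.g. "RA", "RA+AS"), registry evidence columns
#'   `a_<stratum>`, `rr_<stratum>`, and the SRS evidence columns.
#' @export
intersect_signals <- function(novel, annotated) {
  sig <- filter(annotated, .data$significant_any) |>
    distinct(.data$drug, .data$term, .keep_all = TRUE) |>
    select("drug", "term", "srs_a", "prr", "ror", "ic",
           "fdr_prr", "fdr_ror", "fdr_ic")
  strata <- novel |>
    group_by(.data$drug, .data$term) |>
    summarise(diseases = paste(sort(unique(.data$disease)), collapse = "+"),
              .groups = "drop")
  registry_ev <- novel |>
    select("disease", "drug", "term", "a", "rr") |>
    tidyr::pivot_wider(names_from = "disease", values_from = c("a", "rr"),
                       names_glue = "{.value}_{disease}")
  out <- sig |>
    inner_join(strata, by = c("drug", "term")) |>
    left_join(registry_ev, by = c("drug", "term")) |>
    relocate("drug", "term", "diseases") |>
    arrange(.data$drug, .data$term)
  structure(out, class = c("pv_final", class(out)))
}

stage_log <- function(log, stage, rows_in, rows_out) {
  line <- sprintf("stage=%s rows_in=%d rows_out=%d", stage,
                  as.integer(rows_in), as.integer(rows_out))
  inform(line)
  c(log, line)
}

load_pipeline_inputs <- function(config, out_data_dir, seed) {
  if (isTRUE(config$data$demo)) {
    d <- build_demo(seed = seed)
    write_registry_data(d$registry, file.path(out_data_dir, "registry"))
    write_srs_data(d$srs, file.path(out_data_dir, "srs.tsv"))
    write_mappings(d$mappings, file.path(out_data_dir, "mappings"))
    write_label_kb(d$label_kb, file.path(out_data_dir, "label_kb.tsv"))
    write_ehr_data(d$ehr, file.path(out_data_dir, "ehr"))
    write_tsv_file(d$catalog, file.path(out_data_dir, "lab_catalog.tsv"))
    write_tsv_file(d$lab_term_map,
                   file.path(out_data_dir, "lab_term_map.tsv"))
    write_ground_truth(d$truth, file.path(out_data_dir, "ground_truth.json"))
    return(d)
  }
  p <- config$data
  for (f in c("registry_dir", "srs_path", "mappings_dir", "kb_path")) {
    if (!file.exists(p[[f]])) {
      abort(paste0("missing input: ", f, " = ", p[[f]]))
    }
  }
  list(
    registry = read_registry_data(p$registry_dir),
    srs = read_srs_data(p$srs_path),
    mappings = read_mappings(p$mappings_dir),
    label_kb = read_label_kb(p$kb_path),
    ehr = if (!is.null(p$ehr_dir)) read_ehr_data(p$ehr_dir),
    catalog = if (!is.null(p$catalog_path)) read_tsv_file(p$catalog_path),
    lab_term_map = if (!is.null(p$lab_term_map_path)) {
      read_tsv_file(p$lab_term_map_path)
    }
  )
}

#' Run the end-to-end signal-detection pipeline
#'
#' Orchestrates the full analysis: per-disease registry screen, label
#' exclusion, merge of strata, spontaneous-report disproportionality
#' validation, intersection into final signals, and (optionally) the
#' laboratory-abnormality screen as supplementary evidence that annotates
#' but never gates final signals.  Every stage writes its table under a
#' fixed directory layout, a structured log line records input/output row
#' counts per stage, and a JSON manifest records the seed and content
#' hashes.  Identical (config, seed) produces identical outputs.
#'
#' @param config A [pv_config()] or path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return A `pv_run` list with all stage results (`signals`, `novel`,
#'   `excluded`, `candidates`, `dispro`, `annotated`, `lab`, `final`),
#'   the resolved config, the output directory and the flow `counts`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pv_config(config)
  if (!inherits(config, "pv_config")) {
    abort("`config` must be a pv_config or a path to a YAML config file")
  }
  seed <- as.integer(seed %||% config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()

  data_dir <- file.path(out_dir, "00_data")
  dir.create(data_dir, showWarnings = FALSE)
  inputs <- load_pipeline_inputs(config, data_dir, seed)
  log <- stage_log(log, "load_data",
                   nrow(inputs$registry$events), nrow(inputs$srs))

  # stage 1: per-disease registry screen
  cases <- select_valid_cases(inputs$registry, inputs$mappings)
  signals <- screen_registry(cases, alpha = config$alpha,
                             min_count = config$min_count,
                             point_estimate_only = config$point_estimate_only)
  reg_dir <- file.path(out_dir, "01_registry")
  dir.create(reg_dir, showWarnings = FALSE)
  for (dis in unique(signals$disease)) {
    write_tsv_file(filter(signals, .data$disease == dis),
                   file.path(reg_dir, paste0("signals_", dis, ".tsv")))
  }
  log <- stage_log(log, "registry_screen", nrow(cases), nrow(signals))

  # stage 2: label exclusion, per stratum
  part <- filter_novel(signals, inputs$label_kb)
  nov_dir <- file.path(out_dir, "02_novel")
  dir.create(nov_dir, showWarnings = FALSE)
  write_tsv_file(part$novel, file.path(nov_dir, "novel.tsv"))
  write_tsv_file(part$excluded, file.path(nov_dir, "excluded.tsv"))
  log <- stage_log(log, "label_exclusion", sum(signals$significant),
                   nrow(part$novel))

  # stage 3: merge strata into candidate pairs
  candidates <- part$novel |>
    group_by(.data$drug, .data$term) |>
    summarise(diseases = paste(sort(unique(.data$disease)), collapse = "+"),
              .groups = "drop") |>
    arrange(.data$drug, .data$term)
  cand_dir <- file.path(out_dir, "03_candidates")
  dir.create(cand_dir, showWarnings = FALSE)
  write_tsv_file(candidates, file.path(cand_dir, "candidates.tsv"))
  log <- stage_log(log, "merge_strata", nrow(part$novel), nrow(candidates))

  # stage 4: SRS disproportionality and candidate annotation
  srs_dir <- file.path(out_dir, "04_srs")
  dir.create(srs_dir, showWarnings = FALSE)
  tab <- build_case_noncase(inputs$srs, inputs$mappings)
  dispro <- dispro_screen(tab, threshold = config$fdr_threshold,
                          mc_draws = config$mc_draws, seed = seed)
  write_tsv_file(as_tibble(dispro), file.path(srs_dir, "dispro.tsv"))
  annotated <- validate_candidates(candidates, dispro,
                                   threshold = config$fdr_threshold)
  write_tsv_file(annotated, file.path(srs_dir, "candidates_annotated.tsv"))
  log <- stage_log(log, "srs_dispro", nrow(tab),
                   sum(annotated$significant_any))

  # stage 5 (supplementary): laboratory-abnormality screen
  lab <- NULL
  if (config$run_metalab && !is.null(inputs$ehr) &&
      !is.null(inputs$catalog)) {
    lab_dir <- file.path(out_dir, "05_metalab")
    dir.create(lab_dir, showWarnings = FALSE)
    lab <- screen_lab(inputs$ehr, inputs$catalog,
                      window_days = config$window_days,
                      alpha = config$alpha)
    write_tsv_file(as_tibble(lab), file.path(lab_dir, "lab_signals.tsv"))
    log <- stage_log(log, "metalab_screen", nrow(inputs$ehr$exposures),
                     sum(lab$significant))
  }

  # stage 6: intersection into final signals (metalab annotates only)
  final <- intersect_signals(part$novel, annotated)
  if (!is.null(lab) && !is.null(inputs$lab_term_map)) {
    lab_sig <- lab |>
      filter(.data$significant) |>
      inner_join(inputs$lab_term_map, by = "signal_id") |>
      select("drug", "term", metalab_rr = "rr", metalab_p = "p_value")
    final <- left_join(final, lab_sig, by = c("drug", "term"))
  }
  fin_dir <- file.path(out_dir, "06_final")
  dir.create(fin_dir, showWarnings = FALSE)
  write_tsv_file(as_tibble(final), file.path(fin_dir, "final_signals.tsv"))
  by_drug <- final |>
    group_by(.data$drug) |>
    summarise(n_signals = n(),
              signals = paste(.data$term, collapse = "; "),
              .groups = "drop") |>
    arrange(.data$drug)
  write_tsv_file(by_drug, file.path(fin_dir, "final_by_drug.tsv"))
  log <- stage_log(log, "intersection", nrow(candidates), nrow(final))

  writeLines(log, file.path(out_dir, "run_log.txt"))
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!grepl("manifest[.]json$", outputs)]
  manifest <- list(
    package = "pvscreen",
    version = as.character(utils::packageVersion("pvscreen")),
    seed = seed,
    config = unclass(config),
    files = as.list(tools::md5sum(sort(outputs)))
  )
  names(manifest$files) <- sub(paste0("^", out_dir, "/?"), "",
                               names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  counts <- list(
    n_cases = table(cases$disease),
    n_significant = table(filter(signals, .data$significant)$disease),
    n_novel = table(part$novel$disease),
    n_excluded = table(part$excluded$disease),
    n_candidates = nrow(candidates),
    n_srs_confirmed = sum(annotated$significant_any),
    n_final = nrow(final)
  )
  structure(
    list(config = config, out_dir = out_dir, seed = seed, cases = cases,
         signals = signals, novel = part$novel, excluded = part$excluded,
         candidates = candidates, dispro = dispro, annotated = annotated,
         lab = lab, final = final, counts = counts, log = log),
    class = "pv_run"
  )
}
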