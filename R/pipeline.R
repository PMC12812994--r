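# End-to-end orchestration: config -> all output tables + run manifest.

default_pipeline_config <- function() {
  list(synthetic = NULL,             # synth_config() arguments
       bundle_dir = NULL,            # existing bundle instead of synthetic
       dialect = "faers-ascii",
       lexicon = NULL,               # path; NULL = shipped lexicon
       pt_soc = NULL,                # path; NULL = shipped mapping
       soc = "Nervous system disorders",
       criteria = list(),            # signal_criteria() overrides
       top_k = 10,
       sensitivity_drug = "thalidomide",
       seed = 1L)
}

validate_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(config$bundle_dir) && is.null(config$synthetic)) {
    abort("pipeline config needs either 'bundle_dir' or 'synthetic'")
  }
  cfg <- utils::modifyList(base, config)
  if (is.null(cfg$synthetic) && !is.null(config$synthetic)) {
    cfg$synthetic <- list()
  }
  if (!is.null(cfg$bundle_dir) && !dir.exists(cfg$bundle_dir)) {
    abort(paste0("bundle_dir does not exist: ", cfg$bundle_dir))
  }
  bad <- setdiff(names(cfg$criteria),
                 names(formals(signal_criteria)))
  if (length(bad) > 0) {
    abort(paste0("unknown signal criteria key(s): ", paste(bad, collapse = ", ")))
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Ingests (or generates) a report bundle, deduplicates, tags target drugs,
#' maps SOCs, and writes every stage's output table to `outdir`: baseline
#' demographics, the full signal table, top-k frequency and top-k ROR
#' rankings with bubble coordinates, the sex-subgroup volcano table, the
#' Weibull time-to-onset summary with Kaplan-Meier curves and the log-rank
#' test, the concomitant-exclusion sensitivity comparison, and a JSON run
#' manifest with the seed, config and row counts at every stage. All
#' randomness flows from `config$seed`, so a rerun is byte-identical.
#'
#' @param config A list (see the vignette) or a path to a YAML file with
#'   the same keys. Either `synthetic:` (generator arguments) or
#'   `bundle_dir:` must be present.
#' @param outdir Output directory, created if needed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  lexicon <- if (is.null(cfg$lexicon)) read_drug_lexicon() else
    read_drug_lexicon(cfg$lexicon)
  pt_soc <- if (is.null(cfg$pt_soc)) read_pt_soc() else read_pt_soc(cfg$pt_soc)

  if (!is.null(cfg$bundle_dir)) {
    reports <- read_faers_bundle(cfg$bundle_dir, cfg$dialect)
  } else {
    syn_args <- cfg$synthetic
    syn_args$seed <- syn_args$seed %||% cfg$seed
    reports <- synth_generate(do.call(synth_config, syn_args))$reports
  }
  counts$report_versions <- nrow(reports$demo)

  reports <- dedup_reports(reports)
  counts$deduplicated_cases <- nrow(reports$demo)
  reports <- tag_target_reports(reports, lexicon)
  counts$tagged_reports <- nrow(distinct(reports$targets, .data$primaryid))
  reports <- map_soc(reports, pt_soc)

  baseline <- summarize_baseline(reports)
  readr::write_csv(baseline, file.path(outdir, "baseline.csv"), progress = FALSE)

  records <- event_records(reports)
  counts$event_records <- nrow(records)
  criteria <- do.call(signal_criteria, cfg$criteria)
  stats <- signal_stats(records, criteria = criteria)
  soc_stats <- filter(stats, !is.na(.data$soc) & .data$soc == cfg$soc)
  readr::write_csv(soc_stats, file.path(outdir, "signals.csv"), progress = FALSE)
  counts$soc_pairs_scored <- nrow(soc_stats)

  top_freq <- rank_signals(soc_stats, by = "frequency", k = cfg$top_k)
  top_ror <- rank_signals(soc_stats, by = "ror", k = cfg$top_k)
  readr::write_csv(top_freq, file.path(outdir, "top_frequency.csv"), progress = FALSE)
  readr::write_csv(top_ror, file.path(outdir, "top_ror.csv"), progress = FALSE)
  readr::write_csv(bubble_coords(top_ror), file.path(outdir, "bubble.csv"),
                   progress = FALSE)

  soc_records <- restrict_to_soc(records, cfg$soc)
  subgroup <- sex_stratified_ror(soc_records, min_count = 3)
  volcano <- volcano_table(subgroup)
  readr::write_csv(volcano, file.path(outdir, "volcano.csv"), progress = FALSE)

  ttos <- extract_tto(soc_records)
  counts$tto_records <- nrow(ttos)
  tto_tbl <- tto_summary(ttos)
  readr::write_csv(tto_tbl, file.path(outdir, "tto_summary.csv"), progress = FALSE)
  readr::write_csv(km_curve(ttos), file.path(outdir, "km_curves.csv"),
                   progress = FALSE)
  lr <- log_rank(ttos)
  readr::write_csv(lr, file.path(outdir, "log_rank.csv"), progress = FALSE)

  filtered_reports <- exclude_concomitant(reports, cfg$sensitivity_drug, lexicon)
  counts$reports_after_exclusion <- nrow(filtered_reports$demo)
  filtered_stats <- signal_stats(event_records(filtered_reports),
                                 criteria = criteria)
  stability <- compare_runs(
    filter(stats, !is.na(.data$soc) & .data$soc == cfg$soc),
    filter(filtered_stats, !is.na(.data$soc) & .data$soc == cfg$soc))
  readr::write_csv(stability, file.path(outdir, "sensitivity.csv"), progress = FALSE)

  manifest <- list(seed = cfg$seed,
                   soc = cfg$soc,
                   criteria = criteria,
                   config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
                   package_version = as.character(utils::packageVersion("faersignal")),
                   row_counts = counts,
                   flag_agreement_pct = attr(stability, "agreement"),
                   log_rank_p = lr$p_value)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
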