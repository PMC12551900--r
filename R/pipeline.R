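# End-to-end pipeline: ingest -> dedupe -> filter -> group -> map ->
# summarize -> PRR, driven by a YAML configuration and writing a
# deterministic artifact directory.

#' Read and validate a pipeline configuration
#'
#' YAML file with keys: `files` (demo/drug/reac/indi, optional outc),
#' `map` (PT-to-category TSV path), optional `synonyms`, `window`
#' (`start`, `end`), and optional `out_dir`, `indication_patterns`,
#' `countries`, `collapse_duplicates`, `alpha`, `threshold`.
#'
#' @param path Path to a YAML config.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$files)) stop_fmt("config: missing key 'files'")
  for (f in c("demo", "drug", "reac", "indi")) {
    if (is.null(cfg$files[[f]])) {
      stop_fmt("config: files.%s is required", f)
    }
  }
  for (key in c("map", "window")) {
    if (is.null(cfg[[key]])) stop_fmt("config: missing key '%s'", key)
  }
  if (is.null(cfg$window$start) || is.null(cfg$window$end)) {
    stop_fmt("config: window.start and window.end are required")
  }
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$threshold <- cfg$threshold %||% 2
  cfg$collapse_duplicates <- isTRUE(cfg$collapse_duplicates)
  cfg$countries <- cfg$countries %||% US_COUNTRY_CODES
  cfg$indication_patterns <- cfg$indication_patterns %||%
    PROSTATE_INDICATION_PATTERNS
  cfg
}

stage_log <- function(lines, stage, n_in, n_out) {
  c(lines, sprintf("stage=%s in=%d out=%d removed=%d",
                   stage, n_in, n_out, n_in - n_out))
}

#' Run the full pipeline
#'
#' Chains every stage — ingest, deduplicate, eligibility filter, treatment
#' grouping, event mapping, stratified summaries, PRR panel — and writes the
#' artifact directory: `flow.tsv` (filter flow counts),
#' `table_characteristics.tsv`, `table_events_by_age.tsv`,
#' `table_events_by_group.tsv`, `prr_panel.tsv`, `diagnostics.txt`,
#' `pipeline.log` (one structured line per stage), and a `MANIFEST`
#' recording completion state. Re-running on identical inputs and config
#' reproduces byte-identical TSVs (no stage uses randomness).
#'
#' On a stage failure the error names the stage, and the MANIFEST retains the
#' stages that completed.
#'
#' @param config Path to a YAML config, or a list from
#'   [read_pipeline_config()].
#' @param out_dir Artifact directory; overrides the config's `out_dir`.
#' @param dry_run Validate the config and input paths, touch nothing.
#' @return Invisibly, a list with the filtered cases, event table, summary
#'   tables, PRR panel, and flow counts (`NULL` components on `dry_run`).
#' @export
run_pipeline <- function(config, out_dir = NULL, dry_run = FALSE) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir) && !dry_run) {
    stop_fmt("config: out_dir is required (or pass out_dir=)")
  }
  if (dry_run) {
    for (f in c("demo", "drug", "reac", "indi")) {
      if (!file.exists(cfg$files[[f]])) {
        stop_fmt("faers_io: input file not found: %s", cfg$files[[f]])
      }
    }
    if (!file.exists(cfg$map)) {
      stop_fmt("event_mapper: mapping file not found: %s", cfg$map)
    }
    message("dry run: config valid")
    return(invisible(list(config = cfg)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  completed <- character()
  manifest <- file.path(out_dir, "MANIFEST")
  note_done <- function(stage) {
    completed <<- c(completed, stage)
    writeLines(c(sprintf("status: %s",
                         if (length(completed) == 7L) "complete"
                         else "partial"),
                 paste("completed:", completed)), manifest)
  }
  log_lines <- character()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c("status: failed", paste("completed:", completed),
                   sprintf("failed_stage: %s", stage)), manifest)
      stop_fmt("%s: %s", stage, conditionMessage(e))
    })
  }

  synonyms <- if (is.null(cfg$synonyms)) load_drug_synonyms() else
    load_drug_synonyms(cfg$synonyms)

  raw <- run_stage("faers_io", read_faers_quarter(
    cfg$files$demo, cfg$files$drug, cfg$files$reac, cfg$files$indi,
    outc_path = cfg$files$outc, synonyms = synonyms))
  write_diagnostics(raw, file.path(out_dir, "diagnostics.txt"))
  note_done("ingest")

  dedup <- run_stage("faers_io", deduplicate_cases(raw))
  log_lines <- stage_log(log_lines, "dedupe", n_cases(raw), n_cases(dedup))
  note_done("dedupe")

  # Reference database: window + country + age filters only; the cohort adds
  # the prostate-cancer ARPI indication requirement on top. PRR denominators
  # use the reference database, per the "all other reports" comparator.
  ref <- run_stage("cohort_builder", filter_cohort(
    dedup, cfg$window$start, cfg$window$end, countries = cfg$countries,
    indication_patterns = cfg$indication_patterns,
    require_indication = FALSE))
  cohort <- run_stage("cohort_builder", filter_cohort(
    dedup, cfg$window$start, cfg$window$end, countries = cfg$countries,
    indication_patterns = cfg$indication_patterns))
  utils::write.table(cohort$flow, file.path(out_dir, "flow.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- stage_log(log_lines, "filter", n_cases(dedup),
                         n_cases(cohort$cases))
  note_done("filter")

  refc <- run_stage("cohort_builder", assign_groups(ref$cases))
  # Cases eligible for the cohort keep their group; the rest of the
  # reference database is comparator background.
  refc$demo$group[!refc$demo$primaryid %in%
                    cohort$cases$demo$primaryid] <- "excluded"
  log_lines <- stage_log(log_lines, "group", n_cases(refc),
                         sum(refc$demo$group != "excluded"))
  note_done("group")

  map <- run_stage("event_mapper", load_disease_group_map(cfg$map))
  mapped <- run_stage("event_mapper", map_reactions(
    refc, map, collapse_duplicates = cfg$collapse_duplicates))
  events <- run_stage("event_mapper", event_table(mapped))
  log_lines <- stage_log(log_lines, "map", nrow(mapped$reactions),
                         nrow(events))
  note_done("map")

  grouped_cases <- mapped
  grouped_cases$demo <- mapped$demo[mapped$demo$group != "excluded", ,
                                    drop = FALSE]
  tab1 <- run_stage("summarizer", characteristics_table(grouped_cases))
  cohort_events <- events[events$group != "excluded", , drop = FALSE]
  tab2 <- run_stage("summarizer", events_by_stratum(cohort_events,
                                                    "age_band"))
  tab3 <- run_stage("summarizer", events_by_stratum(cohort_events, "group"))
  write_summary_table(tab1, file.path(out_dir, "table_characteristics.tsv"))
  write_summary_table(tab2, file.path(out_dir, "table_events_by_age.tsv"))
  write_summary_table(tab3, file.path(out_dir, "table_events_by_group.tsv"))
  note_done("summarize")

  panel <- run_stage("disproportionality", prr_panel(
    events, alpha = cfg$alpha, threshold = cfg$threshold))
  write_prr_panel(panel, file.path(out_dir, "prr_panel.tsv"))
  log_lines <- stage_log(log_lines, "prr", nrow(events), nrow(panel))
  note_done("prr")

  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(cases = mapped, events = events, flow = cohort$flow,
                 characteristics = tab1, events_by_age = tab2,
                 events_by_group = tab3, panel = panel))
}
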