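#' Run the full signal-detection pipeline
#'
#' Orchestrates every stage: ingest (or take generated bundles) -> window
#' filter -> deduplicate -> exclusions -> cohort split -> term mapping ->
#' 2x2 contingency at PT and SOC level -> the four disproportionality
#' statistics with signal criteria -> descriptive summaries. Flow counts are
#' recorded at every stage so the selection funnel is reconstructible from
#' the run record alone.
#'
#' @param input Either a list of `quarter_bundle`s, a directory containing
#'   FAERS ASCII files (read via [read_quarter_bundles()]), or a
#'   [synthetic_config()] (generated via [generate_reports()]).
#' @param target Canonical id of the study drug.
#' @param synonym_table Drug synonym table; defaults to the shipped
#'   trametinib table, or the configuration-derived table for synthetic
#'   input.
#' @param tm A [term_map()]; defaults to the configuration-derived map for
#'   synthetic input, otherwise identity (PT level only).
#' @param window Optional character vector `c(first, last)` of quarter ids;
#'   bundles outside it are dropped.
#' @param unit Counting unit for [build_contingency()].
#' @param correction,ic_method,criteria Passed to [signal_stats()].
#' @param output_dir Optional directory: all result tables are written as
#'   TSV (with a commented metadata header) plus `run_metadata.json`.
#' @return A `faers_run` list: `cases`, `cohort`, `background`,
#'   `tables_pt`, `tables_soc` (if a term map is available), `signals_pt`,
#'   `signals_soc`, `descriptives`, `flow` (tibble of stage counts),
#'   `metadata`.
#' @export
run_faers_pipeline <- function(input, target = "trametinib",
                               synonym_table = NULL, tm = NULL,
                               window = NULL, unit = c("pair", "report"),
                               correction = FALSE, ic_method = "delta",
                               criteria = signal_criteria(),
                               output_dir = NULL) {
  unit <- match.arg(unit)
  stage <- "ingest"
  tryCatch({
    if (inherits(input, "synthetic_config")) {
      synonym_table <- synonym_table %||% synthetic_synonyms(input)
      tm <- tm %||% synthetic_term_map(input)
      bundles <- generate_reports(input)
    } else if (is.character(input) && length(input) == 1 && dir.exists(input)) {
      bundles <- read_quarter_bundles(input)
    } else {
      bundles <- input
    }
    synonym_table <- synonym_table %||% trametinib_synonyms()
    if (!is.null(window)) {
      stage <- "window"
      ids <- vapply(bundles, function(b) b$quarter_id, character(1))
      bundles <- bundles[ids >= window[1] & ids <= window[2]]
      if (length(bundles) == 0) abort("no bundles inside the study window")
    }
    flow <- tibble(
      stage = "reports_in",
      n = sum(vapply(bundles, function(b) nrow(b$demo), numeric(1)))
    )
    stage <- "deduplicate"
    cases <- deduplicate_cases(bundles)
    flow <- add_row(flow, stage = "reports_deduplicated", n = nrow(cases))
    stage <- "exclusions"
    cases <- apply_exclusions(cases)
    flow <- add_row(flow, stage = "reports_after_exclusion", n = nrow(cases))
    stage <- "cohort"
    split <- select_cohort(cases, target, synonym_table)
    flow <- add_row(flow, stage = "cohort_reports", n = nrow(split$cohort))
    flow <- add_row(flow, stage = "background_reports",
                    n = nrow(split$background))
    stage <- "contingency"
    tables_pt <- build_contingency(split$cohort, split$background, tm,
                                   level = "PT", unit = unit)
    tables_soc <- if (!is.null(tm)) {
      build_contingency(split$cohort, split$background, tm,
                        level = "SOC", unit = unit)
    }
    flow <- add_row(flow, stage = "cohort_event_pairs_pt",
                    n = if (nrow(tables_pt)) tables_pt$a[1] + tables_pt$b[1] else 0)
    flow <- add_row(flow, stage = "distinct_pts", n = sum(tables_pt$a > 0))
    stage <- "statistics"
    signals_pt <- signal_stats(tables_pt, correction = correction,
                               ic_method = ic_method, criteria = criteria)
    signals_soc <- if (!is.null(tables_soc)) {
      signal_stats(tables_soc, correction = correction,
                   ic_method = ic_method, criteria = criteria)
    }
    stage <- "descriptives"
    descr <- describe_cohort(split$cohort, target = target,
                             synonym_table = synonym_table)
    metadata <- list(
      target = target, unit = unit, correction = correction,
      ic_method = ic_method, criteria = criteria,
      dictionary_version = if (!is.null(tm)) tm$version else NA_character_,
      n_bundles = length(bundles),
      denominators = as.list(attr(descr, "denominators")),
      exclusions = as.list(table(attr(cases, "exclusion_log")$reason))
    )
    run <- structure(
      list(
        cases = cases, cohort = split$cohort, background = split$background,
        tables_pt = tables_pt, tables_soc = tables_soc,
        signals_pt = signals_pt, signals_soc = signals_soc,
        descriptives = descr, flow = flow, metadata = metadata
      ),
      class = "faers_run"
    )
    if (!is.null(output_dir)) write_run(run, output_dir)
    run
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })
}

#' @export
print.faers_run <- function(x, ...) {
  cat("<faers_run: target '", x$metadata$target, "'>\n", sep = "")
  print(x$flow)
  invisible(x)
}

write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- run$metadata[c("target", "unit", "correction", "ic_method")]
  write_signal_tsv(run$tables_pt, file.path(dir, "contingency_pt.tsv"), meta)
  write_signal_tsv(tidy(run$signals_pt), file.path(dir, "signals_pt.tsv"),
                   meta)
  if (!is.null(run$signals_soc)) {
    write_signal_tsv(run$tables_soc, file.path(dir, "contingency_soc.tsv"),
                     meta)
    write_signal_tsv(tidy(run$signals_soc), file.path(dir, "signals_soc.tsv"),
                     meta)
  }
  write_signal_tsv(run$descriptives, file.path(dir, "descriptives.tsv"), meta)
  write_signal_tsv(run$flow, file.path(dir, "flow.tsv"), meta)
  jsonlite::write_json(
    c(run$metadata, list(flow = as.list(setNames(run$flow$n, run$flow$stage)))),
    file.path(dir, "run_metadata.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' Rank event terms by count or signal strength
#'
#' Stable sort of a signal table by `a` (report count), EBGM, or ROR, ties
#' broken lexicographically by term; the top-PT charts of pharmacovigilance
#' papers are this table's head.
#'
#' @param results A `faers_signals` tibble.
#' @param by `"count"`, `"ebgm"` or `"ror"`.
#' @param top_k Number of rows to return (all if fewer are available).
#' @param tm Optional [term_map()] to annotate PT rows with their SOC.
#' @return The top rows, with a leading `rank` column.
#' @export
rank_terms <- function(results, by = c("count", "ebgm", "ror"), top_k = 30,
                       tm = NULL) {
  by <- match.arg(by)
  key <- switch(by, count = results$a, ebgm = results$ebgm, ror = results$ror)
  ord <- order(-key, results$term, na.last = TRUE)
  out <- as_tibble(results)[ord, , drop = FALSE]
  out <- head(out, max(top_k, 0))
  if (!is.null(tm) && nrow(out) > 0 && all(out$level == "PT")) {
    out <- mutate(out, soc = roll_up_soc(.data$term, tm), .after = "term")
  }
  mutate(out, rank = row_number(), .before = 1)
}
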