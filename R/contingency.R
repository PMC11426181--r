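#' Build 2x2 contingency tables for every event term
#'
#' For each event term observed anywhere (PT level, or SOC level after
#' rolling up), builds the standard pharmacovigilance four-grid table
#' contrasting target-drug reports against all other reports:
#'
#' * `a` — target drug with the term,
#' * `b` — target drug with other terms,
#' * `c` — other drugs with the term,
#' * `d` — other drugs with other terms.
#'
#' The default counting unit is the report–term pair: each report contributes
#' one count per *distinct* term it carries (duplicate terms within one
#' report collapse), so `a + b` is the total number of cohort report–term
#' pairs and is constant across terms of a level. `unit = "report"` switches
#' to report-level counting (`a + b` = number of cohort reports) for
#' sensitivity analysis.
#'
#' @param cohort,background Case tibbles from [select_cohort()].
#' @param tm A [term_map()]; `NULL` applies the identity mapping (terms
#'   uppercased, SOC level unavailable).
#' @param level `"PT"` or `"SOC"`.
#' @param unit `"pair"` (default) or `"report"`.
#' @return Tibble with columns `term`, `level`, `a`, `b`, `c`, `d`, `n`
#'   (= a+b+c+d), sorted by `a` descending then term; attribute `unit`
#'   records the counting unit.
#' @export
build_contingency <- function(cohort, background, tm = NULL,
                              level = c("PT", "SOC"),
                              unit = c("pair", "report")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  if (is.null(tm)) {
    if (level == "SOC") abort("SOC-level tables require a term_map")
    tm <- term_map(pt_to_soc = character(0))
  }
  pairs <- function(cases) {
    ev <- cases$events
    raw <- unlist(ev, use.names = FALSE)
    if (is.null(raw)) raw <- character(0)
    terms <- map_pt(raw, tm)
    if (level == "SOC") terms <- roll_up_soc(terms, tm)
    tibble(
      caseid = rep(cases$caseid, lengths(ev)),
      term = as.character(terms)
    ) |>
      distinct()
  }
  cp <- pairs(cohort)
  bp <- pairs(background)
  ct <- cp |> count(.data$term, name = "a")
  bt <- bp |> count(.data$term, name = "c")
  tot_c <- if (unit == "pair") nrow(cp) else nrow(cohort)
  tot_b <- if (unit == "pair") nrow(bp) else nrow(background)
  out <- full_join(ct, bt, by = "term") |>
    mutate(
      a = dplyr::coalesce(.data$a, 0L),
      c = dplyr::coalesce(.data$c, 0L),
      level = level,
      b = tot_c - .data$a,
      d = tot_b - .data$c,
      n = .data$a + .data$b + .data$c + .data$d
    ) |>
    select("term", "level", "a", "b", "c", "d", "n") |>
    arrange(desc(.data$a), .data$term)
  attr(out, "unit") <- unit
  out
}
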