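#' Published trametinib summary tables
#'
#' Two published summary tables from the FAERS trametinib analysis
#' (2013Q2–2023Q4, 2200 primary-suspect reports), shipped as plain-text
#' regression inputs:
#'
#' * `published_trametinib_descriptives()` — the descriptive table (yearly
#'   counts, sex, age bands, reporter, country, route, outcomes,
#'   time-to-onset bands) with printed counts and percents. Category
#'   denominators differ: 2200 reports for demographic rows, 2789 outcome
#'   codes for outcome rows, and 1589 onset entries for onset rows (onset
#'   entries are reports with a usable therapy record, a smaller set than
#'   the full cohort).
#' * `published_trametinib_soc_signals()` — the SOC-level signal table: case
#'   reports and the four disproportionality statistics with their interval
#'   bounds, as printed to two decimals.
#'
#' The underlying FAERS extract is not redistributable, so these printed
#' summaries are the reference points for arithmetic and internal-consistency
#' checks (percent recomputation; the identity `IC = log2(EBGM)`).
#'
#' @return A tibble.
#' @export
published_trametinib_descriptives <- function() {
  path <- system.file("extdata", "trametinib_descriptives_published.tsv",
                      package = "faersignal", mustWork = TRUE)
  as_tibble(read.delim(path, sep = "\t", quote = "", comment.char = "#",
                       stringsAsFactors = FALSE)) |>
    mutate(count = as.numeric(.data$count),
           percent = as.numeric(.data$percent))
}

#' @rdname published_trametinib_descriptives
#' @export
published_trametinib_soc_signals <- function() {
  path <- system.file("extdata", "trametinib_soc_signals_published.tsv",
                      package = "faersignal", mustWork = TRUE)
  as_tibble(read.delim(path, sep = "\t", quote = "", comment.char = "#",
                       stringsAsFactors = FALSE)) |>
    mutate(across(-"soc", as.numeric))
}

#' Category denominators of the published descriptive table
#'
#' @return Named numeric vector: reports (2200), outcome codes (2789), onset
#'   entries (1589).
#' @export
published_trametinib_denominators <- function() {
  d <- published_trametinib_descriptives()
  c(
    reports = sum(d$count[d$category == "sex"]),
    outcome_codes = sum(d$count[d$category == "outcome"]),
    onset_entries = sum(d$count[d$category == "onset"])
  )
}
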