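#' Deduplicate cases across quarterly bundles
#'
#' FAERS cases are resubmitted across quarterly releases under the same case
#' identifier; the analysis set keeps only the latest entry for each unique
#' case ID, determined by the FDA receipt date (`fda_dt`). Ties on the date
#' are broken by the larger case version, then by the numerically larger
#' primary identifier. A retained record with no parsable date at all falls
#' back to the highest version/primary identifier; the number of such cases
#' is recorded.
#'
#' Child-table rows (drugs, reactions, outcomes, therapy dates) are attached
#' from the retained version only.
#'
#' @param bundles List of `quarter_bundle`s (see [assemble_quarter_bundle()]).
#' @return A tibble with one row per unique case: columns `caseid`,
#'   `primaryid`, `fda_dt` (integer `YYYYMMDD` or `NA`), `year`, `sex`
#'   (`"F"`, `"M"`, `"unknown"`), `age_years` (`NA` when unknown),
#'   `reporter`, `country`, `event_date` (possibly partial `YYYY[MM[DD]]`
#'   string), and list-columns `drugs` (tibble per case), `events` (distinct
#'   reported terms) and `outcomes` (outcome codes). Rows are sorted by
#'   `caseid`, so the result is invariant to the order of `bundles`.
#'   Attribute `dedup_log` records raw row counts, duplicates removed, and
#'   dateless fallbacks.
#' @export
deduplicate_cases <- function(bundles) {
  stopifnot(length(bundles) > 0)
  get_col <- function(df, col) {
    if (col %in% names(df)) df[[col]] else rep("", nrow(df))
  }
  demo <- bind_rows(lapply(bundles, function(b) {
    tibble(
      primaryid = get_col(b$demo, "primaryid"),
      caseid = get_col(b$demo, "caseid"),
      caseversion = get_col(b$demo, "caseversion"),
      fda_dt = get_col(b$demo, "fda_dt"),
      event_dt = get_col(b$demo, "event_dt"),
      sex = get_col(b$demo, "sex"),
      age = get_col(b$demo, "age"),
      age_cod = get_col(b$demo, "age_cod"),
      occp_cod = get_col(b$demo, "occp_cod"),
      reporter_country = get_col(b$demo, "reporter_country")
    )
  }))
  n_raw <- nrow(demo)
  demo <- demo |>
    mutate(
      fda_num = suppressWarnings(as.numeric(.data$fda_dt)),
      ver_num = suppressWarnings(as.numeric(.data$caseversion)),
      pid_num = suppressWarnings(as.numeric(.data$primaryid))
    ) |>
    arrange(
      .data$caseid,
      desc(!is.na(.data$fda_num)),
      desc(.data$fda_num),
      desc(.data$ver_num),
      desc(.data$pid_num),
      desc(.data$primaryid)
    ) |>
    distinct(.data$caseid, .keep_all = TRUE)
  n_dateless <- sum(is.na(demo$fda_num))
  if (n_dateless > 0) {
    inform(paste0(n_dateless, " case(s) retained by version identifier ",
                  "because no receipt date was parsable"))
  }
  keep_pid <- demo$primaryid

  bind_child <- function(kind, cols) {
    rows <- bind_rows(lapply(bundles, function(b) {
      x <- b[[kind]]
      as_tibble(setNames(lapply(cols, function(cc) get_col(x, cc)), cols))
    }))
    rows[rows$primaryid %in% keep_pid, , drop = FALSE]
  }
  drug <- bind_child("drug", c("primaryid", "caseid", "drug_seq", "role_cod",
                               "drugname", "prod_ai", "route"))
  reac <- bind_child("reac", c("primaryid", "caseid", "pt"))
  outc <- bind_child("outc", c("primaryid", "caseid", "outc_cod"))
  ther <- bind_child("ther", c("primaryid", "caseid", "dsg_drug_seq",
                               "start_dt"))

  # therapy start joined per drug mention via the drug sequence number;
  # NA marks "no therapy record", "" a record with a missing date.
  drug <- drug |>
    left_join(
      ther |>
        select("primaryid", dsg_drug_seq = "dsg_drug_seq",
               therapy_start = "start_dt") |>
        distinct(.data$primaryid, .data$dsg_drug_seq, .keep_all = TRUE),
      by = c("primaryid", drug_seq = "dsg_drug_seq")
    ) |>
    mutate(role = ifelse(.data$role_cod %in% c("PS", "SS", "C", "I"),
                         .data$role_cod, "unknown")) |>
    select("primaryid", "drug_seq", "role", "drugname", "prod_ai", "route",
           "therapy_start")

  drugs_nested <- tidyr::nest(drug, drugs = -"primaryid")
  events_by <- reac |>
    group_by(.data$primaryid) |>
    summarise(events = list(unique(.data$pt[.data$pt != ""])))
  outc_by <- outc |>
    group_by(.data$primaryid) |>
    summarise(outcomes = list(.data$outc_cod[.data$outc_cod != ""]))

  empty_drugs <- tibble(
    drug_seq = character(0), role = character(0), drugname = character(0),
    prod_ai = character(0), route = character(0), therapy_start = character(0)
  )
  cases <- demo |>
    transmute(
      caseid = .data$caseid,
      primaryid = .data$primaryid,
      fda_dt = ifelse(is.na(.data$fda_num), NA_integer_,
                      as.integer(.data$fda_num)),
      year = ifelse(is.na(.data$fda_num), NA_integer_,
                    as.integer(.data$fda_num %/% 10000)),
      sex = ifelse(toupper(.data$sex) %in% c("F", "M"),
                   toupper(.data$sex), "unknown"),
      age_years = age_to_years(.data$age, .data$age_cod),
      reporter = reporter_label(.data$occp_cod),
      country = ifelse(.data$reporter_country == "", "Unknown",
                       .data$reporter_country),
      event_date = .data$event_dt
    ) |>
    left_join(drugs_nested, by = "primaryid") |>
    left_join(events_by, by = "primaryid") |>
    left_join(outc_by, by = "primaryid") |>
    mutate(
      drugs = purrr::map(.data$drugs, \(d) d %||% empty_drugs),
      events = purrr::map(.data$events, \(e) e %||% character(0)),
      outcomes = purrr::map(.data$outcomes, \(o) o %||% character(0))
    ) |>
    arrange(.data$caseid)

  attr(cases, "dedup_log") <- tibble(
    n_raw_demo = n_raw,
    n_cases = nrow(cases),
    n_duplicates_removed = n_raw - nrow(cases),
    n_dateless_fallback = n_dateless
  )
  cases
}

# AGE + AGE_COD -> years. Blank code is taken as years (the common FAERS
# convention); anything unparsable or outside [0, 120] becomes NA (unknown).
age_to_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  factor <- dplyr::case_match(
    toupper(age_cod),
    "DEC" ~ 10,
    c("YR", "") ~ 1,
    "MON" ~ 1 / 12,
    "WK" ~ 1 / 52.18,
    "DY" ~ 1 / 365.25,
    "HR" ~ 1 / 8766,
    .default = NA_real_
  )
  out <- v * factor
  out[is.na(out) | out < 0 | out > 120] <- NA_real_
  out
}

reporter_label <- function(occp_cod) {
  dplyr::case_match(
    toupper(occp_cod),
    "MD" ~ "Physician",
    "PH" ~ "Pharmacist",
    c("OT", "HP", "RN") ~ "Other health professional",
    "CN" ~ "Consumer",
    .default = "Unknown"
  )
}

#' Normalise reported drug names against a synonym table
#'
#' Maps free-text drug name strings (trade names, active-ingredient strings,
#' combination-product expressions) to a canonical drug identifier by exact
#' match — after trimming, whitespace collapsing, and uppercasing — against a
#' synonym table. Substring matching is deliberately not performed: synonym
#' tables enumerate combination products explicitly so that strings like
#' `"TRAMETINIBX"` are not falsely captured.
#'
#' @param name_raw Character vector of reported names.
#' @param synonym_table A data frame with columns `synonym` and `canonical`
#'   (see [read_synonym_table()]), or a named character vector mapping
#'   uppercase synonyms to canonical ids.
#' @return Character vector of canonical ids; non-matches map to `"other"`.
#' @export
#' @examples
#' normalize_drug_name(c("Mekinist", "aspirin"), trametinib_synonyms())
normalize_drug_name <- function(name_raw, synonym_table) {
  lut <- synonym_lookup(synonym_table)
  key <- str_norm(name_raw)
  out <- unname(lut[key])
  out[is.na(out)] <- "other"
  out
}

synonym_lookup <- function(synonym_table) {
  if (is.character(synonym_table)) {
    setNames(unname(synonym_table), str_norm(names(synonym_table)))
  } else {
    setNames(synonym_table$canonical, str_norm(synonym_table$synonym))
  }
}

#' Read a drug-synonym table
#'
#' Two-column tab-separated text file (`synonym`, `canonical`), `#` comments
#' allowed, no header.
#'
#' @param path Path to the file.
#' @return Tibble with columns `synonym`, `canonical`.
#' @export
read_synonym_table <- function(path) {
  as_tibble(read.delim(
    path, header = FALSE, sep = "\t", comment.char = "#", quote = "",
    col.names = c("synonym", "canonical"),
    colClasses = "character", strip.white = TRUE
  ))
}

#' The shipped trametinib synonym table
#'
#' The expressions under which trametinib appears in FAERS drug records:
#' active-ingredient strings ("TRAMETINIB", "TRAMETINIB DIMETHYL SULFOXIDE",
#' the combination string "DABRAFENIB\\TRAMETINIB") and trade/code names
#' ("MEKINIST", "GSK1120212", "TAFINLAR COMBO").
#'
#' @return Tibble with columns `synonym`, `canonical`.
#' @export
trametinib_synonyms <- function() {
  read_synonym_table(
    system.file("extdata", "trametinib_synonyms.tsv", package = "faersignal",
                mustWork = TRUE)
  )
}

#' Split cases into target-drug cohort and background
#'
#' The cohort comprises deduplicated reports in which the target drug appears
#' as a primary suspect (role `PS`), matched on either the active-ingredient
#' or the drug-name field; every other report is background. The two sets
#' partition the input.
#'
#' @param cases Case tibble from [deduplicate_cases()].
#' @param target Canonical drug id, e.g. `"trametinib"`.
#' @param synonym_table Synonym table (see [normalize_drug_name()]).
#' @return List with tibbles `cohort` and `background`.
#' @export
select_cohort <- function(cases, target, synonym_table = trametinib_synonyms()) {
  lut <- synonym_lookup(synonym_table)
  mentions <- tibble(
    case_row = rep(seq_len(nrow(cases)),
                   vapply(cases$drugs, nrow, integer(1))),
    prod_ai = unlist(lapply(cases$drugs, `[[`, "prod_ai"), use.names = FALSE),
    drugname = unlist(lapply(cases$drugs, `[[`, "drugname"),
                      use.names = FALSE),
    role = unlist(lapply(cases$drugs, `[[`, "role"), use.names = FALSE)
  )
  canon <- unname(lut[str_norm(mentions$prod_ai)])
  miss <- is.na(canon)
  canon[miss] <- unname(lut[str_norm(mentions$drugname[miss])])
  is_target_case <- logical(nrow(cases))
  hit_rows <- mentions$case_row[!is.na(canon) & canon == target &
                                  mentions$role == "PS"]
  is_target_case[unique(hit_rows)] <- TRUE
  if (!any(is_target_case)) {
    warn(paste0("empty cohort for target drug '", target,
                "': downstream statistics will be degenerate"))
  }
  list(
    cohort = cases[is_target_case, , drop = FALSE],
    background = cases[!is_target_case, , drop = FALSE]
  )
}

#' Apply the mechanical exclusion rules
#'
#' Removes cases that cannot enter the analysis: cases with no event term at
#' all, and cases whose retained record has no parsable case identifier.
#' Removals are counted by reason and attached as the `exclusion_log`
#' attribute (a tibble of `caseid`, `reason`).
#'
#' @param cases Case tibble from [deduplicate_cases()].
#' @return The retained cases, with attribute `exclusion_log`.
#' @export
apply_exclusions <- function(cases) {
  bad_id <- is.na(cases$caseid) | cases$caseid == ""
  no_event <- lengths(cases$events) == 0L
  log <- bind_rows(
    tibble(caseid = cases$caseid[bad_id], reason = "bad_caseid"),
    tibble(caseid = cases$caseid[!bad_id & no_event], reason = "no_event")
  )
  out <- cases[!bad_id & !no_event, , drop = FALSE]
  if (nrow(log) > 0) {
    inform(paste0("excluded ", nrow(log), " case(s): ",
                  paste(sprintf("%s=%d", names(table(log$reason)),
                                as.integer(table(log$reason))),
                        collapse = ", ")))
  }
  attr(out, "exclusion_log") <- log
  out
}
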