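#' Descriptive summary of a report cohort
#'
#' Produces the standard publication-style descriptive table for one
#' category of a pharmacovigilance cohort: yearly report counts, sex, age
#' bands, reporter occupation, reporting country, administration route of
#' the suspect drug, clinical outcomes, or time-to-onset bands.
#'
#' Denominators differ by category and are part of the contract:
#' `year`/`sex`/`age`/`reporter`/`country`/`route` use the number of cohort
#' reports; `outcome` uses the number of outcome *codes* (a report may carry
#' several); `onset` uses the number of cohort reports with at least one
#' therapy record for the target primary-suspect drug (reports with no
#' therapy record cannot contribute an onset status and are counted in the
#' attribute `n_no_therapy_record`). "Unknown" rows are always reported,
#' never dropped.
#'
#' All bins are left-closed, right-open: a 65-year-old falls in `65-75`; an
#' onset of exactly 7 days falls in `7-28`, exactly 60 days in `>=60`.
#'
#' @param cohort Case tibble (deduplicated).
#' @param category One of `"year"`, `"sex"`, `"age"`, `"reporter"`,
#'   `"country"`, `"route"`, `"outcome"`, `"onset"`.
#' @param target,synonym_table Needed for `route` and `onset`, which refer to
#'   the target drug's primary-suspect mentions.
#' @return Tibble `(category, label, count, percent)`, `percent` rounded
#'   half-up to 2 decimals against the category denominator (attribute
#'   `denominator`).
#' @export
summarize_cohort <- function(cohort,
                             category = c("year", "sex", "age", "reporter",
                                          "country", "route", "outcome",
                                          "onset"),
                             target = "trametinib",
                             synonym_table = trametinib_synonyms()) {
  category <- match.arg(category)
  n_extra <- integer(0)
  if (category == "outcome") {
    codes <- unlist(cohort$outcomes, use.names = FALSE)
    labels <- outcome_label(codes)
    denom <- length(labels)
  } else if (category == "onset") {
    od <- onset_days(cohort, target = target, synonym_table = synonym_table)
    has_record <- od$status != "no_therapy_record"
    n_extra <- c(n_no_therapy_record = sum(!has_record))
    labels <- onset_bin(od$days[has_record])
    denom <- sum(has_record)
  } else {
    labels <- switch(
      category,
      year = ifelse(is.na(cohort$year), "Unknown", as.character(cohort$year)),
      sex = dplyr::case_match(cohort$sex, "F" ~ "Female", "M" ~ "Male",
                              .default = "Unknown"),
      age = age_bin(cohort$age_years),
      reporter = cohort$reporter,
      country = cohort$country,
      route = ps_route(cohort, target, synonym_table)
    )
    denom <- nrow(cohort)
  }
  out <- tibble(category = category, label = labels) |>
    count(.data$category, .data$label, name = "count") |>
    mutate(percent = round_half_up(100 * .data$count / denom, 2)) |>
    arrange(desc(.data$count), .data$label)
  if (category == "year") out <- arrange(out, .data$label)
  attr(out, "denominator") <- denom
  attr(out, "n_extra") <- n_extra
  out
}

age_bin <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "Unknown",
    age_years < 18 ~ "<18",
    age_years < 45 ~ "18-45",
    age_years < 65 ~ "45-65",
    age_years < 75 ~ "65-75",
    TRUE ~ ">=75"
  )
}

onset_bin <- function(days) {
  dplyr::case_when(
    is.na(days) ~ "Unknown",
    days < 7 ~ "<7",
    days < 28 ~ "7-28",
    days < 60 ~ "28-60",
    TRUE ~ ">=60"
  )
}

outcome_label <- function(code) {
  dplyr::case_match(
    toupper(code),
    "DE" ~ "Death",
    "LT" ~ "Life-threatening",
    "HO" ~ "Hospitalization",
    "DS" ~ "Disability",
    "CA" ~ "Congenital anomaly",
    "RI" ~ "Required intervention to prevent permanent impairment/damage",
    .default = "Other serious"
  )
}

# Administration route of the first primary-suspect mention of the target
# drug; reports whose PS mention lacks a route (or has none) are "Unknown".
ps_route <- function(cohort, target, synonym_table) {
  lut <- synonym_lookup(synonym_table)
  vapply(cohort$drugs, function(d) {
    if (is.null(d) || nrow(d) == 0) return("Unknown")
    canon <- unname(lut[str_norm(d$prod_ai)])
    miss <- is.na(canon)
    canon[miss] <- unname(lut[str_norm(d$drugname[miss])])
    hit <- which(!is.na(canon) & canon == target & d$role == "PS")
    if (length(hit) == 0) return("Unknown")
    r <- d$route[hit[1]]
    if (is.na(r) || r == "") "Unknown" else tools::toTitleCase(tolower(r))
  }, character(1))
}

#' Time from therapy start to event, per report
#'
#' For each cohort report, the onset time in days is the event date minus
#' the earliest therapy start among the report's primary-suspect mentions of
#' the target drug. Both dates must carry full year-month-day precision;
#' partial dates give an unknown onset, and a negative difference (event
#' before therapy start) is treated as inconsistent and also unknown.
#'
#' @param cohort Case tibble.
#' @param target Canonical drug id.
#' @param synonym_table Synonym table for drug-name matching.
#' @return Tibble `(caseid, days, status)` where `status` is one of `"ok"`,
#'   `"partial_date"`, `"inconsistent"` (negative difference),
#'   `"no_therapy_record"`; `days` is `NA` unless `status == "ok"`.
#' @export
onset_days <- function(cohort, target = "trametinib",
                       synonym_table = trametinib_synonyms()) {
  lut <- synonym_lookup(synonym_table)
  res <- purrr::map2(cohort$drugs, cohort$event_date, function(d, ev) {
    if (is.null(d) || nrow(d) == 0) {
      return(list(days = NA_real_, status = "no_therapy_record"))
    }
    canon <- unname(lut[str_norm(d$prod_ai)])
    miss <- is.na(canon)
    canon[miss] <- unname(lut[str_norm(d$drugname[miss])])
    hit <- !is.na(canon) & canon == target & d$role == "PS" &
      !is.na(d$therapy_start)
    if (!any(hit)) {
      return(list(days = NA_real_, status = "no_therapy_record"))
    }
    starts <- d$therapy_start[hit]
    full <- starts[!is.na(parse_full_date(starts))]
    if (length(full) == 0 || is.na(parse_full_date(ev))) {
      return(list(days = NA_real_, status = "partial_date"))
    }
    s <- min(parse_full_date(full))
    days <- as.numeric(parse_full_date(ev) - s)
    if (days < 0) {
      return(list(days = NA_real_, status = "inconsistent"))
    }
    list(days = days, status = "ok")
  })
  tibble(
    caseid = cohort$caseid,
    days = vapply(res, function(r) r$days, numeric(1)),
    status = vapply(res, function(r) r$status, character(1))
  )
}

# Parse a FAERS date string to Date; only full-precision YYYYMMDD values
# parse, partial dates (YYYY or YYYYMM) and anything malformed return NA.
parse_full_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out
}

#' Combined descriptive report
#'
#' Runs [summarize_cohort()] for every category and stacks the results into
#' one publication-style table.
#'
#' @inheritParams summarize_cohort
#' @param categories Categories to include, in order.
#' @return Tibble `(category, label, count, percent)` with attribute
#'   `denominators` (named vector).
#' @export
describe_cohort <- function(cohort, target = "trametinib",
                            synonym_table = trametinib_synonyms(),
                            categories = c("year", "sex", "age", "reporter",
                                           "country", "route", "outcome",
                                           "onset")) {
  parts <- lapply(categories, function(cc) {
    summarize_cohort(cohort, cc, target = target,
                     synonym_table = synonym_table)
  })
  out <- bind_rows(parts)
  attr(out, "denominators") <- setNames(
    vapply(parts, function(p) attr(p, "denominator"), numeric(1)), categories
  )
  out
}
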