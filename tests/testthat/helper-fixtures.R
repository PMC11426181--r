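# Builders for tiny in-code fixtures and independently coded oracles.

# A minimal DEMO row set; extra columns appended via ...
demo_rows <- function(primaryid, caseid, fda_dt, caseversion = "1", ...) {
  tibble::tibble(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    caseversion = as.character(caseversion),
    fda_dt = as.character(fda_dt),
    ...
  )
}

drug_rows <- function(primaryid, caseid, drugname, role_cod = "PS",
                      drug_seq = "1", prod_ai = drugname, route = "ORAL") {
  tibble::tibble(
    primaryid = as.character(primaryid), caseid = as.character(caseid),
    drug_seq = as.character(drug_seq), role_cod = role_cod,
    drugname = drugname, prod_ai = prod_ai, route = route
  )
}

reac_rows <- function(primaryid, caseid, pt) {
  tibble::tibble(primaryid = as.character(primaryid),
                 caseid = as.character(caseid), pt = pt)
}

make_bundle <- function(quarter_id, demo, drug = NULL, reac = NULL,
                        outc = NULL, ther = NULL) {
  assemble_quarter_bundle(
    list(demo = demo, drug = drug, reac = reac, outc = outc, ther = ther),
    quarter_id
  )
}

# Independent naive evaluator of the four statistics: proportion/odds
# arithmetic done step by step, chi-squared delegated to stats::chisq.test.
naive_stats <- function(a, b, c, d) {
  n <- a + b + c + d
  odds_t <- (a / (a + b)) / (b / (a + b))
  odds_o <- (c / (c + d)) / (d / (c + d))
  p_t <- a / (a + b)
  p_o <- c / (c + d)
  expected <- (a + b) * (a + c) / n
  list(
    ror = odds_t / odds_o,
    prr = p_t / p_o,
    chi2 = unname(suppressWarnings(stats::chisq.test(
      matrix(c(a, b, c, d), 2, byrow = TRUE), correct = FALSE
    ))$statistic),
    ic = (log(a) - log(expected)) / log(2),
    ebgm = a / expected
  )
}

# Nested-loop recount of report-term pairs, the brute-force oracle for
# build_contingency (pair counting unit).
naive_contingency <- function(cohort, background, tm, level) {
  terms_of <- function(case_events) {
    pts <- map_pt(case_events, tm)
    if (level == "SOC") pts <- roll_up_soc(pts, tm)
    unique(as.character(pts))
  }
  co <- lapply(cohort$events, terms_of)
  bg <- lapply(background$events, terms_of)
  all_terms <- sort(unique(c(unlist(co), unlist(bg))))
  tot_co <- sum(lengths(co))
  tot_bg <- sum(lengths(bg))
  out <- lapply(all_terms, function(tt) {
    a <- 0; cc <- 0
    for (e in co) if (tt %in% e) a <- a + 1
    for (e in bg) if (tt %in% e) cc <- cc + 1
    tibble::tibble(term = tt, a = a, b = tot_co - a, c = cc, d = tot_bg - cc)
  })
  dplyr::bind_rows(out)
}

# Shared 50k-report null-model run (lambda = 1 everywhere), generated once
# per test session; used by the calibration and type-I checks.
null_model_cache <- new.env(parent = emptyenv())

null_model_results <- function() {
  if (!is.null(null_model_cache$res)) return(null_model_cache$res)
  cfg <- synthetic_config(
    seed = 42, n_reports = 50000, n_quarters = 12,
    signals = tibble::tibble(drug = character(), pt = character(),
                             lambda = numeric())
  )
  bundles <- generate_reports(cfg)
  cases <- suppressMessages(apply_exclusions(
    suppressMessages(deduplicate_cases(bundles))
  ))
  syn <- synthetic_synonyms(cfg)
  tm <- synthetic_term_map(cfg)
  res <- dplyr::bind_rows(lapply(cfg$drugs$drug, function(g) {
    sp <- suppressWarnings(select_cohort(cases, g, syn))
    tt <- build_contingency(sp$cohort, sp$background, tm, level = "PT")
    dplyr::mutate(signal_stats(tt), drug = g)
  }))
  null_model_cache$res <- list(config = cfg, results = res)
  null_model_cache$res
}

# Planted-signal recovery configuration: one rare PT boosted fivefold for
# the target drug, sized so the pair accrues about a hundred reports.
recovery_config <- function(seed = 7) {
  synthetic_config(
    seed = seed, n_reports = 5000, n_quarters = 8,
    signals = tibble::tibble(drug = "trametinib", pt = "VISION BLURRED",
                             lambda = 5),
    p_no_event = 0
  )
}
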