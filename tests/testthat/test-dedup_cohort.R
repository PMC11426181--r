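two_version_bundles <- function(dt1 = "20150110", dt2 = "20150705",
                                pid2 = "12") {
  b1 <- make_bundle(
    "2015q1",
    demo_rows("11", "1", dt1, caseversion = "1", sex = "F"),
    drug = drug_rows("11", "1", "MEKINIST"),
    reac = reac_rows("11", "1", "PYREXIA")
  )
  b2 <- make_bundle(
    "2015q3",
    demo_rows(pid2, "1", dt2, caseversion = "2", sex = "M"),
    drug = drug_rows(pid2, "1", "TRAMETINIB"),
    reac = reac_rows(pid2, "1", "RASH")
  )
  list(b1, b2)
}

test_that("the version with the latest receipt date is retained", {
  cases <- deduplicate_cases(two_version_bundles())
  expect_equal(nrow(cases), 1L)
  expect_equal(cases$primaryid, "12")
  expect_equal(cases$sex, "M")
  # child rows come from the retained version only
  expect_equal(cases$events[[1]], "RASH")
  expect_equal(cases$drugs[[1]]$drugname, "TRAMETINIB")
})

test_that("date ties break to the larger primary identifier", {
  cases <- deduplicate_cases(two_version_bundles(dt1 = "20150110",
                                                 dt2 = "20150110"))
  expect_equal(cases$primaryid, "12")
})

test_that("a dateless retained case falls back to the version identifier", {
  expect_message(
    cases <- deduplicate_cases(two_version_bundles(dt1 = "", dt2 = "")),
    "version identifier"
  )
  expect_equal(cases$primaryid, "12")
  expect_true(is.na(cases$fda_dt))
})

test_that("synthetic resubmissions collapse to exactly one case each", {
  cfg <- synthetic_config(seed = 11, n_reports = 100, n_quarters = 4,
                          resubmission_rate = 0.3)
  bundles <- generate_reports(cfg)
  n_raw <- sum(vapply(bundles, function(b) nrow(b$demo), numeric(1)))
  expect_gt(n_raw, 100)
  cases <- deduplicate_cases(bundles)
  expect_equal(nrow(cases), 100L)
  expect_equal(attr(cases, "dedup_log")$n_duplicates_removed, n_raw - 100L)
  # resubmitted cases retain version 2
  resub <- cases[grepl("2$", cases$primaryid), ]
  expect_equal(nrow(resub), n_raw - 100L)
})

test_that("deduplication is invariant to bundle order", {
  cfg <- synthetic_config(seed = 13, n_reports = 150, n_quarters = 5,
                          resubmission_rate = 0.4)
  bundles <- generate_reports(cfg)
  a <- deduplicate_cases(bundles)
  b <- deduplicate_cases(rev(bundles))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("drug names normalise by exact match after trimming and casing", {
  syn <- trametinib_synonyms()
  expect_equal(normalize_drug_name("Mekinist", syn), "trametinib")
  expect_equal(normalize_drug_name("  mekinist  ", syn), "trametinib")
  expect_equal(normalize_drug_name("TRAMETINIB DIMETHYL  SULFOXIDE", syn),
               "trametinib")
  expect_equal(normalize_drug_name("DABRAFENIB\\TRAMETINIB", syn),
               "trametinib")
  expect_equal(normalize_drug_name("TRAMETINIBX", syn), "other")
  expect_equal(normalize_drug_name("", syn), "other")
  # total and idempotent over arbitrary inputs
  inputs <- c("GSK1120212", "tafinlar combo", "aspirin", NA, "  ", "$weird")
  out <- normalize_drug_name(inputs, syn)
  expect_length(out, length(inputs))
  expect_false(anyNA(out))
  expect_equal(normalize_drug_name(out, syn), out)
})

test_that("cohort selection requires the primary-suspect role", {
  demo <- demo_rows(c("11", "21", "31"), c("1", "2", "3"),
                    rep("20200101", 3))
  drug <- dplyr::bind_rows(
    drug_rows("11", "1", "MEKINIST", role_cod = "C"),
    drug_rows("21", "2", "TRAMETINIB", role_cod = "PS"),
    drug_rows("21", "2", "ASPIRIN", role_cod = "C", drug_seq = "2"),
    drug_rows("21", "2", "OMEPRAZOLE", role_cod = "C", drug_seq = "3"),
    drug_rows("31", "3", "NIVOLUMAB", role_cod = "PS")
  )
  reac <- reac_rows(c("11", "21", "31"), c("1", "2", "3"),
                    c("PYREXIA", "RASH", "NAUSEA"))
  cases <- deduplicate_cases(list(make_bundle("2020q1", demo, drug = drug,
                                              reac = reac)))
  sp <- select_cohort(cases, "trametinib")
  expect_equal(sp$cohort$caseid, "2")        # PS wins, concomitants ignored
  expect_setequal(sp$background$caseid, c("1", "3"))  # role C is background
  # conservation: the split partitions the input
  expect_equal(nrow(sp$cohort) + nrow(sp$background), nrow(cases))
  expect_length(intersect(sp$cohort$caseid, sp$background$caseid), 0)
})

test_that("an empty cohort warns and yields an empty split", {
  cases <- deduplicate_cases(two_version_bundles())
  expect_warning(sp <- select_cohort(cases, "nonexistent-drug"),
                 "empty cohort")
  expect_equal(nrow(sp$cohort), 0L)
  expect_equal(nrow(sp$background), nrow(cases))
})

test_that("planted primary-suspect cases are all captured", {
  cfg <- synthetic_config(seed = 5, n_reports = 2000, n_quarters = 6,
                          p_no_event = 0)
  bundles <- generate_reports(cfg)
  cases <- deduplicate_cases(bundles)
  sp <- select_cohort(cases, "trametinib", synthetic_synonyms(cfg))
  # the generator knows exactly which caseids got the target as PS
  got <- sort(sp$cohort$caseid)
  want <- sort(unique(unlist(lapply(bundles, function(b) {
    b$drug$caseid[b$drug$role_cod == "PS" &
                    (b$drug$prod_ai == "TRAMETINIB" |
                       b$drug$drugname %in%
                       trametinib_synonyms()$synonym)]
  }))))
  expect_equal(got, want)
})

test_that("exclusions remove eventless and id-less cases, with a log", {
  demo <- demo_rows(as.character(11:20), as.character(1:10),
                    rep("20200101", 10))
  demo$caseid[10] <- ""
  reac <- reac_rows(as.character(11:18), as.character(1:8),
                    rep("PYREXIA", 8))
  expect_message(
    cases <- apply_exclusions(
      deduplicate_cases(list(make_bundle("2020q1", demo, reac = reac)))
    ),
    "excluded"
  )
  expect_equal(nrow(cases), 8L)
  log <- attr(cases, "exclusion_log")
  expect_setequal(log$reason, c("no_event", "bad_caseid"))
  expect_equal(sum(log$reason == "no_event"), 1L)
})

test_that("ages convert to years across all unit codes", {
  expect_equal(
    age_to_years(c("5.5", "45", "18", "26", "730", "96", ""),
                 c("DEC", "YR", "MON", "WK", "DY", "HR", "YR")),
    c(55, 45, 1.5, 26 / 52.18, 730 / 365.25, 96 / 8766, NA_real_)
  )
  # blank unit code means years; impossible values become unknown
  expect_equal(age_to_years("64", ""), 64)
  expect_true(is.na(age_to_years("130", "YR")))
  expect_true(is.na(age_to_years("-4", "YR")))
  expect_true(is.na(age_to_years("forty", "YR")))
})
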