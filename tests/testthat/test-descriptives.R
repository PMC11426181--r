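# A hand-built cohort: six trametinib PS cases with controlled demographics,
# outcomes, therapy and event dates.
descriptive_cohort <- function() {
  demo <- tibble::tibble(
    primaryid = as.character(11:16),
    caseid = as.character(1:6),
    caseversion = "1",
    fda_dt = c("20200115", "20200220", "20210310", "20210405", "20220501",
               "20220601"),
    event_dt = c("20200115", "202002", "20210308", "20210315", "20220430",
                 "20220520"),
    sex = c("F", "M", "", "F", "F", "M"),
    age = c("64", "65", "17", "", "8.1", "30"),
    age_cod = c("YR", "YR", "YR", "", "DEC", "MON"),
    occp_cod = c("MD", "MD", "PH", "CN", "", "OT"),
    reporter_country = c("United States", "France", "", "United States",
                         "Japan", "France")
  )
  drug <- drug_rows(demo$primaryid, demo$caseid, "TRAMETINIB",
                    route = c("ORAL", "ORAL", "", "INTRAVENOUS", "ORAL",
                              "ORAL"))
  reac <- reac_rows(demo$primaryid, demo$caseid, rep("PYREXIA", 6))
  outc <- tibble::tibble(
    primaryid = c("11", "11", "12", "13", "14", "15", "16"),
    caseid = c("1", "1", "2", "3", "4", "5", "6"),
    outc_cod = c("HO", "DE", "HO", "OT", "LT", "OT", "HO")
  )
  # case 1: onset 14d; case 2: month-precision event date; case 3: negative
  # (event before start); case 4: full, 0d; case 5: no therapy row;
  # case 6: partial (month) start date.
  ther <- tibble::tibble(
    primaryid = c("11", "12", "13", "14", "16"),
    caseid = c("1", "2", "3", "4", "6"),
    dsg_drug_seq = "1",
    start_dt = c("20200101", "20200201", "20210310", "20210315", "202205")
  )
  cases <- deduplicate_cases(list(make_bundle(
    "2020q1", demo, drug = drug, reac = reac, outc = outc, ther = ther
  )))
  select_cohort(cases, "trametinib")$cohort
}

test_that("onset days follow the full-precision, non-negative contract", {
  od <- onset_days(descriptive_cohort())
  expect_equal(od$status,
               c("ok", "partial_date", "inconsistent", "ok",
                 "no_therapy_record", "partial_date"))
  expect_equal(od$days, c(14, NA, NA, 0, NA, NA))
})

test_that("onset bins are left-closed right-open at 7, 28 and 60 days", {
  expect_equal(
    faersignal:::onset_bin(c(0, 6, 7, 27, 28, 59, 60, 400, NA)),
    c("<7", "<7", "7-28", "7-28", "28-60", "28-60", ">=60", ">=60",
      "Unknown")
  )
  expect_equal(faersignal:::age_bin(c(0, 17.9, 18, 44, 45, 64.99, 65, 74,
                                      75, 119, NA)),
               c("<18", "<18", "18-45", "18-45", "45-65", "45-65", "65-75",
                 "65-75", ">=75", ">=75", "Unknown"))
})

test_that("category summaries use the documented denominators", {
  cohort <- descriptive_cohort()
  sex <- summarize_cohort(cohort, "sex")
  expect_equal(attr(sex, "denominator"), 6)
  expect_equal(sex$count[sex$label == "Female"], 3L)
  expect_equal(sex$percent[sex$label == "Female"], 50)
  expect_equal(sex$count[sex$label == "Unknown"], 1L)

  age <- summarize_cohort(cohort, "age")
  # 64 -> 45-65; 65 -> 65-75 (left-closed); 17 -> <18; DEC 8.1 -> 81 ->=75;
  # MON 30 -> 2.5y -> <18; missing -> Unknown
  expect_equal(age$count[age$label == "45-65"], 1L)
  expect_equal(age$count[age$label == "65-75"], 1L)
  expect_equal(age$count[age$label == "<18"], 2L)
  expect_equal(age$count[age$label == ">=75"], 1L)
  expect_equal(age$count[age$label == "Unknown"], 1L)

  # outcome rows count codes, not reports: 7 codes over 6 reports
  outc <- summarize_cohort(cohort, "outcome")
  expect_equal(attr(outc, "denominator"), 7)
  expect_equal(outc$count[outc$label == "Hospitalization"], 3L)
  expect_equal(outc$percent[outc$label == "Hospitalization"],
               round(100 * 3 / 7, 2))

  # onset denominator excludes the case with no therapy record
  onset <- summarize_cohort(cohort, "onset")
  expect_equal(attr(onset, "denominator"), 5)
  expect_equal(attr(onset, "n_extra")[["n_no_therapy_record"]], 1L)
  expect_equal(sum(onset$count), 5L)
  expect_equal(onset$count[onset$label == "Unknown"], 3L)

  route <- summarize_cohort(cohort, "route")
  expect_equal(route$count[route$label == "Oral"], 4L)
  expect_equal(route$count[route$label == "Unknown"], 1L)
})

test_that("percent columns sum to 100 within rounding slack", {
  cohort <- descriptive_cohort()
  for (cat in c("year", "sex", "age", "reporter", "country", "route",
                "outcome", "onset")) {
    s <- summarize_cohort(cohort, cat)
    expect_lt(abs(sum(s$percent) - 100), 0.05 + 1e-9)
  }
  one <- summarize_cohort(cohort[1, ], "sex")
  expect_equal(one$percent, 100)
})

test_that("printed percentages recompute from printed counts", {
  # the published descriptive table's own arithmetic, at 2 decimals
  expect_equal(faersignal:::round_half_up(100 * 522 / 2200), 23.73)
  expect_equal(faersignal:::round_half_up(100 * 1043 / 2789), 37.40)
  expect_equal(faersignal:::round_half_up(100 * (95 + 353) / 1589), 28.19)
  expect_equal(faersignal:::round_half_up(100 * 3 / 2789), 0.11)
  expect_equal(faersignal:::round_half_up(100 * 1000 / 2200), 45.45)
})

test_that("the combined report stacks every category once", {
  cohort <- descriptive_cohort()
  d <- describe_cohort(cohort)
  expect_setequal(unique(d$category),
                  c("year", "sex", "age", "reporter", "country", "route",
                    "outcome", "onset"))
  expect_equal(attr(d, "denominators")[["outcome"]], 7)
})
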