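tab <- function(a, b, c, d) tibble::tibble(a = a, b = b, c = c, d = d)

test_that("the worked 2x2 example reproduces all four statistics", {
  s <- signal_stats(tab(10, 20, 30, 240))
  expect_equal(s$ror, 4)
  expect_equal(s$ror_lo, 1.712, tolerance = 5e-4)
  expect_equal(s$ror_hi, 9.346, tolerance = 5e-4)
  expect_equal(s$prr, 3)
  expect_equal(s$chi2, 11.538, tolerance = 5e-4)
  expect_equal(s$ic, log2(2.5))
  expect_equal(s$ebgm, 2.5)
  expect_true(s$ror_signal)   # CI low 1.71 > 1 and a >= 3
  expect_true(s$prr_signal)   # 3 >= 2 and 11.5 >= 4
})

test_that("independence tables give the null value of every statistic", {
  s <- signal_stats(tab(10, 90, 100, 900))
  expect_equal(s$prr, 1)
  expect_equal(s$chi2, 0)
  expect_equal(s$ebgm, 1)
  expect_equal(s$ic, 0)
  expect_false(any(s$ror_signal, s$prr_signal, s$bcpnn_signal,
                   s$mgps_signal))
  # symmetric table
  expect_equal(signal_stats(tab(5, 5, 5, 5))$ror, 1)
})

test_that("zero cells make statistics not-evaluable, never silently wrong", {
  s <- signal_stats(tab(0, 30, 30, 240))
  expect_true(is.na(s$ror))
  expect_true(is.na(s$ic))
  expect_true(is.na(s$ebgm))
  expect_false(any(s$ror_signal, s$bcpnn_signal, s$mgps_signal))
  # b = 0 is inside the PRR domain
  s2 <- signal_stats(tab(3, 0, 30, 240))
  expect_equal(s2$prr, 3 * 270 / (3 * 30))
  expect_true(is.na(s2$ror))
  # continuity correction makes the zero-cell table evaluable
  s3 <- signal_stats(tab(0, 30, 30, 240), correction = TRUE)
  expect_equal(s3$ror, (0.5 * 240.5) / (30.5 * 30.5))
  # degenerate one-cell universe: IC = log of 1 = 0
  s4 <- signal_stats(tab(1, 0, 0, 0))
  expect_equal(s4$ic, 0)
  expect_equal(s4$ic_v, 0)
})

test_that("the case-count gate blocks sparse pairs however large the ROR", {
  s <- signal_stats(tab(2, 1, 1, 1000))
  expect_gt(s$ror, 100)
  expect_false(s$ror_signal)
  expect_false(s$prr_signal)
})

test_that("every statistic matches a naive evaluator over all small tables", {
  grid <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
  s <- signal_stats(grid)
  for (i in seq_len(nrow(grid))) {
    o <- naive_stats(grid$a[i], grid$b[i], grid$c[i], grid$d[i])
    expect_equal(s$ror[i], o$ror, tolerance = 1e-12)
    expect_equal(s$prr[i], o$prr, tolerance = 1e-12)
    expect_equal(s$chi2[i], o$chi2, tolerance = 1e-12)
    expect_equal(s$ic[i], o$ic, tolerance = 1e-12)
    expect_equal(s$ebgm[i], o$ebgm, tolerance = 1e-12)
  }
})

test_that("IC and EBGM are the same quantity on two scales", {
  set.seed(4)
  g <- tab(sample(1:500, 200, TRUE), sample(1:5000, 200, TRUE),
           sample(1:5000, 200, TRUE), sample(1:50000, 200, TRUE))
  s <- signal_stats(g)
  expect_equal(s$ic, log2(s$ebgm))
})

test_that("all statistics increase strictly in a with b, c, d fixed", {
  s <- signal_stats(tab(5:50, 200, 300, 5000))
  expect_true(all(diff(s$ror) > 0))
  expect_true(all(diff(s$prr) > 0))
  expect_true(all(diff(s$ic) > 0))
  expect_true(all(diff(s$ebgm) > 0))
})

test_that("swapping the drug labels inverts the reporting odds ratio", {
  s1 <- signal_stats(tab(7, 13, 29, 511))
  s2 <- signal_stats(tab(29, 511, 7, 13))
  expect_equal(s2$ror, 1 / s1$ror)
  expect_equal(s2$chi2, s1$chi2)  # chi-squared is label-symmetric
})

test_that("delta-method and Monte-Carlo IC025 agree at reporting scale", {
  tabs <- tab(
    a = c(10, 10, 15, 12, 20, 50, 100),
    b = c(100, 150, 90, 300, 180, 450, 900),
    c = c(100, 400, 200, 120, 500, 900, 2000),
    d = c(2000, 8000, 4000, 9000, 10000, 20000, 40000)
  )
  delta <- signal_stats(tabs)$ic025
  mc <- withr::with_seed(
    1, signal_stats(tabs, ic_method = "mc", mc_draws = 1e5)$ic025
  )
  expect_true(all(abs(delta - mc) < 0.1))
})

test_that("criteria thresholds are overridable", {
  s <- signal_stats(tab(10, 20, 30, 240),
                    criteria = signal_criteria(min_cases = 11))
  expect_false(s$ror_signal)
  s2 <- apply_signal_criteria(s, signal_criteria(ebgm05_gt = 1))
  expect_true(s2$mgps_signal)
})

test_that("bare 2x2 TSVs round-trip through the statistics interface", {
  f <- withr::local_tempfile(fileext = ".tsv")
  x <- tibble::tibble(term = c("X", "Y"), level = "PT",
                      a = c(10, 3), b = c(20, 27), c = c(30, 15),
                      d = c(240, 255))
  write_signal_tsv(x, f, meta = list(unit = "pair"))
  back <- read_contingency_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(x))
  s <- signal_stats(back)
  expect_equal(s$ror[1], 4)
})
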