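#' Disproportionality statistics for 2x2 pharmacovigilance tables
#'
#' Computes, for each 2x2 table `(a, b, c, d)` with `N = a+b+c+d`, the four
#' standard disproportionality measures with 95% intervals:
#'
#' * **ROR** — reporting odds ratio `ad/(bc)`, interval
#'   `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`;
#' * **PRR** — proportional reporting ratio `a(c+d)/(c(a+b))`, with the
#'   uncorrected chi-squared
#'   `(ad - bc)^2 N / ((a+b)(c+d)(a+c)(b+d))`, interval
#'   `exp(ln PRR +/- 1.96 * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`;
#' * **IC** — BCPNN information component
#'   `log2(aN / ((a+b)(a+c)))`, the base-2 log of the observed-to-expected
#'   reporting ratio under independence. `E(IC)` is the point value and
#'   `V(IC)` the delta-method variance
#'   `(1/ln 2)^2 (1/a - 1/(a+b) - 1/(a+c) + 1/N)`; the signal bound is
#'   `IC025 = E(IC) - 2 sqrt(V(IC))`. A Monte-Carlo Dirichlet evaluation is
#'   available via `ic_method = "mc"` (see [bcpnn_mc()]).
#' * **EBGM** — the relative reporting ratio `aN / ((a+c)(a+b))` (the
#'   unshrunken observed/expected ratio; note `IC = log2(EBGM)` identically),
#'   interval `exp(ln EBGM +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' A statistic whose formula hits a zero cell is *not evaluable*: it is
#' returned as `NA` and its signal flag is `FALSE` — never silently dropped.
#' `correction = TRUE` applies the Haldane–Anscombe correction (adds 0.5 to
#' every cell of tables containing a zero) before evaluation; the default is
#' off, matching the plain formulas above.
#'
#' @param tables Tibble with columns `a`, `b`, `c`, `d` (and optionally
#'   `term`, `level`, carried through), e.g. from [build_contingency()].
#' @param correction Apply the 0.5 continuity correction to zero-cell tables.
#' @param ic_method `"delta"` (closed form, default) or `"mc"` (Monte-Carlo
#'   Dirichlet quantile for IC025).
#' @param mc_draws Number of Monte-Carlo draws when `ic_method = "mc"`.
#' @param yates Use the Yates-corrected chi-squared instead of the plain
#'   formula (default off).
#' @param criteria Signal thresholds, see [signal_criteria()].
#' @return A `faers_signals` tibble: the input columns plus `ror`, `ror_lo`,
#'   `ror_hi`, `prr`, `prr_lo`, `prr_hi`, `chi2`, `ic`, `ic025`, `ic_e`,
#'   `ic_v`, `ebgm`, `ebgm05`, `ebgm95`, and logical flags `ror_signal`,
#'   `prr_signal`, `bcpnn_signal`, `mgps_signal`. Attribute `meta` records
#'   the correction, IC method and criteria used.
#' @export
#' @examples
#' signal_stats(tibble::tibble(term = "X", a = 10, b = 20, c = 30, d = 240))
signal_stats <- function(tables, correction = FALSE,
                         ic_method = c("delta", "mc"), mc_draws = 1e5,
                         yates = FALSE, criteria = signal_criteria()) {
  ic_method <- match.arg(ic_method)
  x <- as_tibble(tables)
  stopifnot(all(c("a", "b", "c", "d") %in% names(x)))
  a0 <- as.numeric(x$a); b0 <- as.numeric(x$b)
  c0 <- as.numeric(x$c); d0 <- as.numeric(x$d)
  if (any(c(a0, b0, c0, d0) < 0, na.rm = TRUE)) {
    abort("contingency cells must be non-negative")
  }
  zero <- a0 == 0 | b0 == 0 | c0 == 0 | d0 == 0
  if (correction) {
    adj <- ifelse(zero, 0.5, 0)
    a <- a0 + adj; b <- b0 + adj; c <- c0 + adj; d <- d0 + adj
  } else {
    a <- a0; b <- b0; c <- c0; d <- d0
  }
  n <- a + b + c + d

  # computed on the (possibly corrected) numeric cells, outside data masking
  se_all <- all_cells_se(a, b, c, d)
  prr_se <- ifelse(a > 0 & c > 0 & (c + d) > 0 & (a + b) > 0,
                   suppressWarnings(sqrt(1 / a - 1 / (a + b) +
                                           1 / c - 1 / (c + d))),
                   NA_real_)
  res <- x
  res$ror <- ror_point(a, b, c, d)
  res$ror_lo <- exp(log(res$ror) - 1.96 * se_all)
  res$ror_hi <- exp(log(res$ror) + 1.96 * se_all)
  res$prr <- prr_point(a, b, c, d)
  res$prr_lo <- exp(log(res$prr) - 1.96 * prr_se)
  res$prr_hi <- exp(log(res$prr) + 1.96 * prr_se)
  res$chi2 <- chi2_point(a, b, c, d, yates = yates)
  res$ic <- ic_point(a, b, c, d)
  res$ic_e <- res$ic
  res$ic_v <- ic_variance(a, b, c, d)
  res$ebgm <- ebgm_point(a, b, c, d)
  res$ebgm05 <- exp(log(res$ebgm) - 1.96 * se_all)
  res$ebgm95 <- exp(log(res$ebgm) + 1.96 * se_all)
  if (ic_method == "delta") {
    res$ic025 <- res$ic_e - 2 * sqrt(res$ic_v)
  } else {
    res$ic025 <- bcpnn_mc(a, b, c, d, n_draws = mc_draws)$ic025
  }
  res <- relocate(res, "ic025", .after = "ic")
  res <- apply_signal_criteria(res, criteria)
  class(res) <- c("faers_signals", class(res))
  attr(res, "meta") <- list(
    correction = correction, ic_method = ic_method, yates = yates,
    criteria = criteria
  )
  res
}

ror_point <- function(a, b, c, d) {
  ifelse(a > 0 & b > 0 & c > 0 & d > 0, (a * d) / (b * c), NA_real_)
}

prr_point <- function(a, b, c, d) {
  ifelse(c > 0 & (a + b) > 0, (a * (c + d)) / (c * (a + b)), NA_real_)
}

chi2_point <- function(a, b, c, d, yates = FALSE) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  num <- if (yates) {
    (pmax(abs(a * d - b * c) - n / 2, 0))^2 * n
  } else {
    (a * d - b * c)^2 * n
  }
  ifelse(denom > 0, num / denom, NA_real_)
}

ic_point <- function(a, b, c, d) {
  n <- a + b + c + d
  ifelse(a > 0 & (a + b) > 0 & (a + c) > 0,
         log2(a * n / ((a + b) * (a + c))), NA_real_)
}

# Delta-method variance of the information component, in bits^2. Clamped at
# zero: degenerate tables (e.g. b = c = 0) can drive the expression negative.
ic_variance <- function(a, b, c, d) {
  n <- a + b + c + d
  v <- ifelse(a > 0,
              (1 / log(2))^2 * (1 / a - 1 / (a + b) - 1 / (a + c) + 1 / n),
              NA_real_)
  pmax(v, 0)
}

ebgm_point <- function(a, b, c, d) {
  n <- a + b + c + d
  ifelse(a > 0 & (a + b) > 0 & (a + c) > 0,
         a * n / ((a + c) * (a + b)), NA_real_)
}

all_cells_se <- function(a, b, c, d) {
  ifelse(a > 0 & b > 0 & c > 0 & d > 0,
         sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
}

#' Monte-Carlo Dirichlet evaluation of the information component interval
#'
#' Draws the cell probabilities of each 2x2 table from a Dirichlet posterior
#' with parameters `(a, b, c, d) + 1/2` (Jeffreys-type prior), evaluates
#' `IC = log2(p11 / (p1. * p.1))` per draw, and returns the empirical 2.5%
#' quantile. This is the simulation counterpart of the closed-form
#' delta-method bound and serves as its independent cross-check.
#'
#' @param a,b,c,d Numeric vectors of cell counts (recycled to equal length).
#' @param n_draws Draws per table.
#' @return Tibble with columns `ic_median` and `ic025` (bits).
#' @export
bcpnn_mc <- function(a, b, c, d, n_draws = 1e5) {
  m <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, m); b <- rep_len(b, m)
  c <- rep_len(c, m); d <- rep_len(d, m)
  out <- purrr::map(seq_len(m), function(i) {
    g <- matrix(rgamma(4 * n_draws, shape = c(a[i], b[i], c[i], d[i]) + 0.5),
                nrow = 4)
    p <- sweep(g, 2, colSums(g), "/")
    ic <- log2(p[1, ] / ((p[1, ] + p[2, ]) * (p[1, ] + p[3, ])))
    tibble(ic_median = stats::median(ic),
           ic025 = unname(quantile(ic, 0.025)))
  })
  bind_rows(out)
}

#' Signal criteria thresholds
#'
#' The conventional decision rules applied to each method:
#'
#' * ROR: lower 95% bound `> 1` and at least `min_cases` reports of the pair;
#' * PRR: `PRR >= 2`, chi-squared `>= 4`, and at least `min_cases` reports;
#' * BCPNN: `IC025 > 0`;
#' * MGPS: `EBGM05 > 2`.
#'
#' The case-count gate is applied to `a` (reports of the drug–event pair);
#' the four-grid table's own `N = a+b+c+d` would make a total-count reading
#' vacuous.
#'
#' @param min_cases Minimum `a` for the ROR and PRR rules.
#' @param ror_lo_gt,prr_ge,chi2_ge,ic025_gt,ebgm05_gt Thresholds.
#' @return Named list of thresholds.
#' @export
signal_criteria <- function(min_cases = 3, ror_lo_gt = 1, prr_ge = 2,
                            chi2_ge = 4, ic025_gt = 0, ebgm05_gt = 2) {
  list(min_cases = min_cases, ror_lo_gt = ror_lo_gt, prr_ge = prr_ge,
       chi2_ge = chi2_ge, ic025_gt = ic025_gt, ebgm05_gt = ebgm05_gt)
}

#' Apply signal criteria to computed statistics
#'
#' Adds (or recomputes) the per-method logical flags. A statistic that was
#' not evaluable (`NA`) yields `FALSE`.
#'
#' @param res Tibble with the statistic columns of [signal_stats()].
#' @param criteria From [signal_criteria()].
#' @return `res` with columns `ror_signal`, `prr_signal`, `bcpnn_signal`,
#'   `mgps_signal`.
#' @export
apply_signal_criteria <- function(res, criteria = signal_criteria()) {
  flag <- function(x) !is.na(x) & x
  res |>
    mutate(
      ror_signal = flag(.data$ror_lo > criteria$ror_lo_gt &
                          .data$a >= criteria$min_cases),
      prr_signal = flag(.data$prr >= criteria$prr_ge &
                          .data$chi2 >= criteria$chi2_ge &
                          .data$a >= criteria$min_cases),
      bcpnn_signal = flag(.data$ic025 > criteria$ic025_gt),
      mgps_signal = flag(.data$ebgm05 > criteria$ebgm05_gt)
    )
}

#' Read or write bare 2x2 tables as TSV
#'
#' The statistics stage is format-agnostic: any externally supplied TSV of
#' `(term, level, a, b, c, d)` can be scored.
#'
#' @param path TSV path.
#' @return [read_contingency_tsv()]: a tibble suitable for [signal_stats()].
#' @export
read_contingency_tsv <- function(path) {
  as_tibble(read.delim(path, sep = "\t", quote = "", comment.char = "#",
                       stringsAsFactors = FALSE)) |>
    mutate(across(any_of(c("a", "b", "c", "d", "n")), as.numeric))
}

#' @rdname read_contingency_tsv
#' @param x Tibble to write.
#' @param meta Optional named list written as commented header lines.
#' @export
write_signal_tsv <- function(x, path, meta = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(paste0("# ", names(meta), ": ",
                      vapply(meta, function(v) paste(format(v), collapse = ","),
                             character(1))), con)
  }
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x) > 0) {
    body <- do.call(paste, c(lapply(x, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
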