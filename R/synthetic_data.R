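#' Configuration for the synthetic spontaneous-report generator
#'
#' Defines the generative model of a FAERS-like database: background drug
#' and event marginals, planted disproportionality signals, resubmission
#' and missingness rates. The generator draws, for each report, one primary
#' suspect (PS) drug from the drug marginals and a set of distinct preferred
#' terms whose probabilities are the event marginals multiplied by the
#' planted rate multiplier `lambda` for that (drug, PT) pair and
#' renormalised; `lambda = 1` everywhere is the null model. The seed fully
#' determines the output.
#'
#' Default demographics and missingness emulate the structure of real
#' spontaneous-report data: about 13% of reports lack sex, 24% lack age, and
#' 14% of therapy records carry only partial start dates.
#'
#' @param seed Integer seed.
#' @param n_reports Number of unique cases.
#' @param n_quarters Number of quarterly bundles.
#' @param start_quarter First quarter, `"YYYYqQ"`.
#' @param drugs Tibble `(drug, prob)` of PS-drug marginals (renormalised to
#'   sum to 1).
#' @param events Tibble `(pt, soc, prob)` of event marginals (renormalised).
#' @param signals Tibble `(drug, pt, lambda)` of planted multipliers,
#'   `lambda > 0`; pairs not listed have `lambda = 1`.
#' @param resubmission_rate Probability that a case is resubmitted under the
#'   same case id with a later receipt date and higher version.
#' @param missingness Named list with elements `sex`, `age`, `onset` —
#'   probabilities of a missing sex, missing age, and a partial (hence
#'   unusable) therapy start date.
#' @param p_no_event Probability that a report carries no event term (such
#'   reports are later removed by [apply_exclusions()]).
#' @param events_per_report List `(mean, max)`: the distinct-PT count per
#'   report is `1 + min(Poisson(mean - 1), max - 1)`.
#' @param concomitant_mean Poisson mean of additional non-PS drug mentions.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_reports = 5000L,
                             n_quarters = 8L,
                             start_quarter = "2013q2",
                             drugs = default_drug_marginals(),
                             events = default_event_vocabulary(),
                             signals = default_planted_signals(),
                             resubmission_rate = 0.25,
                             missingness = list(sex = 0.13, age = 0.24,
                                                onset = 0.14),
                             p_no_event = 0.02,
                             events_per_report = list(mean = 2.5, max = 8),
                             concomitant_mean = 1) {
  drugs <- as_tibble(drugs)
  events <- as_tibble(events)
  signals <- as_tibble(signals)
  stopifnot(
    all(c("drug", "prob") %in% names(drugs)),
    all(c("pt", "soc", "prob") %in% names(events)),
    nrow(signals) == 0 || all(c("drug", "pt", "lambda") %in% names(signals)),
    all(drugs$prob > 0), all(events$prob > 0),
    nrow(signals) == 0 || all(signals$lambda > 0),
    events_per_report$mean >= 1, events_per_report$max >= 1,
    resubmission_rate >= 0, resubmission_rate <= 1,
    p_no_event >= 0, p_no_event < 1
  )
  if (nrow(signals) > 0 &&
      (!all(signals$drug %in% drugs$drug) || !all(signals$pt %in% events$pt))) {
    abort("planted signals must refer to configured drugs and PTs")
  }
  drugs$prob <- drugs$prob / sum(drugs$prob)
  events$prob <- events$prob / sum(events$prob)
  structure(
    list(
      seed = as.integer(seed), n_reports = as.integer(n_reports),
      n_quarters = as.integer(n_quarters), start_quarter = start_quarter,
      drugs = drugs, events = events, signals = signals,
      resubmission_rate = resubmission_rate, missingness = missingness,
      p_no_event = p_no_event, events_per_report = events_per_report,
      concomitant_mean = concomitant_mean
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config: seed ", x$seed, ", ", x$n_reports, " reports, ",
      nrow(x$drugs), " drugs, ", nrow(x$events), " PTs, ",
      nrow(x$signals), " planted signal(s)>\n", sep = "")
  invisible(x)
}

#' Default marginals for the synthetic generator
#'
#' Six antineoplastic PS drugs (the target among them), a 30-term PT
#' vocabulary spread over 8 organ classes with marginal probabilities in a
#' moderate range (no extremely rare terms, so every drug–PT pair accrues a
#' stable count at realistic database sizes), and three planted trametinib
#' signals of the kind the method is meant to flag.
#'
#' @return `default_drug_marginals()`: tibble `(drug, prob)`;
#'   `default_event_vocabulary()`: tibble `(pt, soc, prob)`;
#'   `default_planted_signals()`: tibble `(drug, pt, lambda)`.
#' @export
default_drug_marginals <- function() {
  tibble(
    drug = c("trametinib", "vemurafenib", "nivolumab", "pembrolizumab",
             "ipilimumab", "dacarbazine"),
    prob = c(0.10, 0.22, 0.20, 0.18, 0.18, 0.12)
  )
}

#' @rdname default_drug_marginals
#' @export
default_event_vocabulary <- function() {
  socs <- c(
    gen = "General disorders and administration site conditions",
    neo = "Neoplasms benign, malignant and unspecified (incl cysts and polyps)",
    inv = "Investigations",
    gi = "Gastrointestinal disorders",
    inf = "Infections and infestations",
    skin = "Skin and subcutaneous tissue disorders",
    card = "Cardiac disorders",
    eye = "Eye disorders"
  )
  pts <- tibble(
    pt = c(
      "PYREXIA", "FATIGUE", "ASTHENIA", "OEDEMA PERIPHERAL", "CHILLS",
      "MALIGNANT NEOPLASM PROGRESSION", "METASTASES TO LIVER",
      "TUMOUR HAEMORRHAGE",
      "EJECTION FRACTION DECREASED", "BLOOD CREATINE PHOSPHOKINASE INCREASED",
      "ALANINE AMINOTRANSFERASE INCREASED", "WEIGHT DECREASED",
      "DIARRHOEA", "NAUSEA", "VOMITING", "ABDOMINAL PAIN", "STOMATITIS",
      "PNEUMONIA", "SEPSIS", "URINARY TRACT INFECTION", "CELLULITIS",
      "RASH", "DERMATITIS ACNEIFORM", "PRURITUS", "DRY SKIN", "CHEILITIS",
      "CARDIAC FAILURE", "ATRIAL FIBRILLATION",
      "ULCERATIVE KERATITIS", "VISION BLURRED"
    ),
    soc = unname(socs[c(
      "gen", "gen", "gen", "gen", "gen",
      "neo", "neo", "neo",
      "inv", "inv", "inv", "inv",
      "gi", "gi", "gi", "gi", "gi",
      "inf", "inf", "inf", "inf",
      "skin", "skin", "skin", "skin", "skin",
      "card", "card",
      "eye", "eye"
    )])
  )
  w <- seq(47, 20, length.out = nrow(pts))
  pts$prob <- w / sum(w)
  pts
}

#' @rdname default_drug_marginals
#' @export
default_planted_signals <- function() {
  tibble(
    drug = "trametinib",
    pt = c("PYREXIA", "EJECTION FRACTION DECREASED", "CHEILITIS"),
    lambda = c(3, 4, 3.5)
  )
}

# Drug-specific PT distribution: marginal x lambda, renormalised per drug.
signal_adjusted_probs <- function(config) {
  q <- sapply(config$drugs$drug, function(g) {
    w <- config$events$prob
    if (nrow(config$signals) > 0) {
      s <- config$signals[config$signals$drug == g, ]
      if (nrow(s) > 0) {
        idx <- match(s$pt, config$events$pt)
        w[idx] <- w[idx] * s$lambda
      }
    }
    w / sum(w)
  })
  rownames(q) <- config$events$pt
  q  # PT x drug matrix
}

# P(K = k) for the distinct-PT slot count K = 1 + min(Poisson(mean-1), max-1).
events_per_report_pmf <- function(config) {
  mu <- config$events_per_report$mean - 1
  mx <- config$events_per_report$max
  k <- seq_len(mx)
  p <- stats::dpois(k - 1, mu)
  p[mx] <- 1 - stats::ppois(mx - 2, mu)
  setNames(p, k)
}

#' Generate a synthetic FAERS-like database
#'
#' Draws the full report structure — versioned resubmissions, PS drug plus
#' concomitants, one-to-many report/event and report/outcome relations,
#' therapy and event dates with partial-date missingness, demographics with
#' configured unknown mass — and packages it as quarterly bundles in the
#' same form that [read_quarter_bundles()] produces from disk. With
#' `dir` set, the bundles are also written in the FAERS ASCII dialect, so
#' the pipeline is agnostic about data origin.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory for the ASCII files.
#' @return List of `quarter_bundle`s.
#' @export
generate_reports <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  bundles <- withr::with_seed(config$seed, generate_reports_impl(config))
  if (!is.null(dir)) write_quarter_bundles(bundles, dir)
  bundles
}

generate_reports_impl <- function(config) {
  n <- config$n_reports
  nq <- config$n_quarters
  qinfo <- quarter_sequence(config$start_quarter, nq)

  caseid <- as.character(10000000L + seq_len(n))
  qidx <- sample.int(nq, n, replace = TRUE)
  fda_date <- qinfo$start[qidx] + sample.int(90, n, replace = TRUE) - 1L

  ps_drug <- sample(config$drugs$drug, n, replace = TRUE,
                    prob = config$drugs$prob)

  # distinct event terms per report
  q <- signal_adjusted_probs(config)
  eventless <- runif(n) < config$p_no_event
  k <- 1L + pmin(rpois(n, config$events_per_report$mean - 1),
                 config$events_per_report$max - 1L)
  k[eventless] <- 0L
  ev_pairs <- vector("list", ncol(q))
  for (gi in seq_len(ncol(q))) {
    g <- colnames(q)[gi]
    rows <- which(ps_drug == g & k > 0)
    if (length(rows) == 0) next
    draws <- sample(rownames(q), sum(k[rows]), replace = TRUE, prob = q[, gi])
    ev_pairs[[gi]] <- tibble(row = rep(rows, k[rows]), pt = draws) |>
      distinct()
  }
  ev <- bind_rows(ev_pairs) |> arrange(.data$row, .data$pt)

  # demographics
  ms <- config$missingness
  sex <- sample(c("F", "M", ""), n, replace = TRUE,
                prob = c(0.52 * (1 - ms$sex), 0.48 * (1 - ms$sex), ms$sex))
  age_known <- runif(n) >= ms$age
  bin <- sample.int(5, n, replace = TRUE,
                    prob = c(0.176, 0.150, 0.357, 0.203, 0.114))
  lo <- c(0, 18, 45, 65, 75)[bin]
  hi <- c(18, 45, 65, 75, 95)[bin]
  age_yr <- floor(runif(n, lo, hi))
  cod_pick <- sample.int(3, n, replace = TRUE, prob = c(0.92, 0.05, 0.03))
  age <- ifelse(!age_known, "",
                ifelse(cod_pick == 1, as.character(age_yr),
                       ifelse(cod_pick == 2, as.character(age_yr / 10),
                              as.character(age_yr * 12))))
  age_cod <- ifelse(!age_known, "",
                    c("YR", "DEC", "MON")[cod_pick])
  occp <- sample(c("MD", "PH", "OT", "CN", ""), n, replace = TRUE,
                 prob = c(0.620, 0.178, 0.145, 0.052, 0.005))
  country <- sample(
    c("United States", "", "France", "Germany", "United Kingdom", "Italy",
      "Australia", "Canada"),
    n, replace = TRUE,
    prob = c(0.32, 0.29, 0.11, 0.07, 0.06, 0.055, 0.05, 0.045)
  )

  # event and therapy dates
  event_date <- fda_date - sample.int(60, n, replace = TRUE) + 1L
  event_dt <- format_partial_date(
    event_date,
    precision = sample(c("D", "M", "Y"), n, replace = TRUE,
                       prob = c(0.94, 0.05, 0.01))
  )
  has_ther <- runif(n) < 0.92
  onset_bin_pick <- sample.int(4, n, replace = TRUE,
                               prob = c(0.07, 0.26, 0.23, 0.44))
  onset <- c(
    sample(0:6, n, replace = TRUE),
    sample(7:27, n, replace = TRUE),
    sample(28:59, n, replace = TRUE),
    60L + as.integer(floor(rexp(n, 1 / 120)))
  )[seq_len(n) + (onset_bin_pick - 1L) * n]
  start_date <- event_date - onset
  start_partial <- runif(n) < ms$onset
  start_dt <- format_partial_date(
    start_date,
    precision = ifelse(!start_partial, "D",
                       ifelse(runif(n) < 0.7, "M", "Y"))
  )
  start_dt[!has_ther] <- NA_character_

  # outcomes: one code always, a second distinct code sometimes
  oc_codes <- c("OT", "HO", "DE", "LT", "DS", "RI", "CA")
  oc_prob <- c(0.458, 0.374, 0.118, 0.035, 0.014, 0.0007, 0.0003)
  oc1 <- sample(oc_codes, n, replace = TRUE, prob = oc_prob)
  second <- runif(n) < 0.27
  oc2 <- sample(oc_codes, n, replace = TRUE, prob = oc_prob)
  oc2[!second | oc2 == oc1] <- NA_character_

  # drug mentions: one PS row plus Poisson-many concomitants
  ps_name <- drug_display_name(ps_drug)
  route <- sample(c("ORAL", "INTRAVENOUS", "SUBCUTANEOUS", ""), n,
                  replace = TRUE, prob = c(0.69, 0.20, 0.05, 0.06))
  n_con <- rpois(n, config$concomitant_mean)
  con_pool <- c("ASPIRIN", "PARACETAMOL", "OMEPRAZOLE", "METFORMIN",
                "ATORVASTATIN", "DEXAMETHASONE")
  con <- tibble(
    row = rep(seq_len(n), n_con),
    drugname = sample(con_pool, sum(n_con), replace = TRUE),
    role_cod = sample(c("C", "SS", "I"), sum(n_con), replace = TRUE,
                      prob = c(0.8, 0.15, 0.05))
  ) |>
    group_by(.data$row) |>
    mutate(drug_seq = as.character(1L + row_number())) |>
    ungroup()

  reports <- tibble(
    row = seq_len(n), caseid = caseid, qidx = qidx, fda_date = fda_date,
    event_dt = event_dt, sex = sex, age = age, age_cod = age_cod,
    occp_cod = occp, reporter_country = country, ps_drug = ps_drug,
    ps_name = ps_name, route = route, start_dt = start_dt, oc1 = oc1,
    oc2 = oc2
  )

  # resubmissions: same caseid, version 2, later receipt date
  resub <- reports[runif(n) < config$resubmission_rate, ]
  if (nrow(resub) > 0) {
    shift <- sample(30:200, nrow(resub), replace = TRUE)
    resub$fda_date <- resub$fda_date + shift
    resub$qidx <- pmin(
      findInterval(as.integer(resub$fda_date), as.integer(qinfo$start)), nq
    )
  }
  versions <- bind_rows(
    mutate(reports, caseversion = "1"),
    mutate(resub, caseversion = "2")
  ) |>
    mutate(primaryid = paste0(.data$caseid, .data$caseversion))

  demo <- versions |>
    transmute(
      qidx = .data$qidx,
      primaryid = .data$primaryid, caseid = .data$caseid,
      caseversion = .data$caseversion,
      fda_dt = format(.data$fda_date, "%Y%m%d"),
      event_dt = .data$event_dt, sex = .data$sex, age = .data$age,
      age_cod = .data$age_cod, occp_cod = .data$occp_cod,
      reporter_country = .data$reporter_country
    )
  ver_key <- versions |> select("row", "qidx", "primaryid", "caseid")

  drug_rows <- bind_rows(
    versions |>
      transmute(.data$row, drug_seq = "1", role_cod = "PS",
                drugname = .data$ps_name,
                prod_ai = toupper(.data$ps_drug), route = .data$route),
    con |>
      transmute(.data$row, .data$drug_seq, .data$role_cod, .data$drugname,
                prod_ai = .data$drugname, route = "")
  ) |>
    inner_join(ver_key, by = "row", relationship = "many-to-many") |>
    select("qidx", "primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "prod_ai", "route") |>
    arrange(.data$primaryid, .data$drug_seq)

  reac_rows <- ev |>
    inner_join(ver_key, by = "row", relationship = "many-to-many") |>
    select("qidx", "primaryid", "caseid", "pt") |>
    arrange(.data$primaryid, .data$pt)

  outc_rows <- bind_rows(
    versions |> transmute(.data$row, outc_cod = .data$oc1),
    versions |> filter(!is.na(.data$oc2)) |>
      transmute(.data$row, outc_cod = .data$oc2)
  ) |>
    inner_join(ver_key, by = "row", relationship = "many-to-many") |>
    select("qidx", "primaryid", "caseid", "outc_cod") |>
    arrange(.data$primaryid, .data$outc_cod)

  ther_rows <- versions |>
    filter(!is.na(.data$start_dt)) |>
    transmute(.data$qidx, .data$primaryid, .data$caseid,
              dsg_drug_seq = "1", start_dt = .data$start_dt) |>
    arrange(.data$primaryid)

  occupied <- sort(unique(demo$qidx))
  lapply(occupied, function(qi) {
    assemble_quarter_bundle(
      list(
        demo = demo |> filter(.data$qidx == qi) |> select(-"qidx"),
        drug = drug_rows |> filter(.data$qidx == qi) |> select(-"qidx"),
        reac = reac_rows |> filter(.data$qidx == qi) |> select(-"qidx"),
        outc = outc_rows |> filter(.data$qidx == qi) |> select(-"qidx"),
        ther = ther_rows |> filter(.data$qidx == qi) |> select(-"qidx")
      ),
      quarter_id = qinfo$quarter_id[qi]
    )
  })
}

# Reported drug-name strings: the target drug appears under its various
# trade/ingredient expressions, as in real data.
drug_display_name <- function(ps_drug) {
  tram <- c("TRAMETINIB", "MEKINIST", "TRAMETINIB DIMETHYL SULFOXIDE",
            "DABRAFENIB\\TRAMETINIB", "GSK1120212", "TAFINLAR COMBO")
  out <- toupper(ps_drug)
  is_t <- ps_drug == "trametinib"
  out[is_t] <- sample(tram, sum(is_t), replace = TRUE)
  out
}

quarter_sequence <- function(start_quarter, n_quarters) {
  y <- as.integer(substr(start_quarter, 1, 4))
  q <- as.integer(substr(start_quarter, 6, 6))
  idx <- (y * 4L + (q - 1L)) + seq_len(n_quarters) - 1L
  tibble(
    quarter_id = paste0(idx %/% 4L, "q", idx %% 4L + 1L),
    start = as.Date(paste(idx %/% 4L, (idx %% 4L) * 3L + 1L, 1L, sep = "-"))
  )
}

format_partial_date <- function(date, precision) {
  full <- format(date, "%Y%m%d")
  ifelse(precision == "D", full,
         ifelse(precision == "M", substr(full, 1, 6), substr(full, 1, 4)))
}

#' Synonym table and term map for a synthetic configuration
#'
#' The generator's vocabulary is closed, so its synonym table (covering the
#' target drug's trade-name expressions and every other configured drug) and
#' its PT-to-SOC map are derivable from the configuration. Every generated
#' PT maps to a SOC: no term is UNMAPPED.
#'
#' @param config A [synthetic_config()].
#' @return `synthetic_synonyms()`: tibble `(synonym, canonical)`;
#'   `synthetic_term_map()`: a [term_map()].
#' @export
synthetic_synonyms <- function(config) {
  base <- tibble(
    synonym = toupper(config$drugs$drug),
    canonical = config$drugs$drug
  )
  if ("trametinib" %in% config$drugs$drug) {
    base <- bind_rows(trametinib_synonyms(), base) |>
      distinct(.data$synonym, .keep_all = TRUE)
  }
  base
}

#' @rdname synthetic_synonyms
#' @export
synthetic_term_map <- function(config) {
  term_map(pt_to_soc = config$events |> select(pt = "pt", soc = "soc"),
           version = "synthetic")
}

#' Analytic ground truth for a synthetic configuration
#'
#' For each (drug, PT) pair, the exact expected pair count and expected
#' relative reporting ratio under the generative model. With `K` event slots
#' per report (`K = 1 + min(Poisson(mean-1), max-1)`) drawn with replacement
#' from the drug-adjusted PT distribution `q` and collapsed to distinct
#' terms, the per-report inclusion probability of PT `j` under drug `g` is
#' `pi = E_K[1 - (1 - q_gj)^K]`, so `E[a] = n (1 - p0) p_g pi` exactly, and
#' the expected relative reporting ratio is formed from the expected margins.
#' Under `lambda = 1` everywhere the expected ratio is exactly 1 for every
#' pair.
#'
#' @param config A [synthetic_config()].
#' @return Tibble `(drug, pt, soc, q, expected_a, expected_ebgm)`;
#'   `expected_ebgm` is `NA` in a single-drug universe (no background).
#' @export
ground_truth <- function(config) {
  q <- signal_adjusted_probs(config)  # PT x drug
  pk <- events_per_report_pmf(config)
  ks <- as.integer(names(pk))
  pi_mat <- apply(q, c(1, 2), function(qq) {
    sum(pk * (1 - (1 - qq)^ks))
  })
  n_eff <- config$n_reports * (1 - config$p_no_event)
  ea <- sweep(pi_mat, 2, config$drugs$prob, "*") * n_eff
  row_g <- colSums(ea)          # expected pairs per drug (a+b)
  col_j <- rowSums(ea)          # expected pairs per PT (a+c)
  n_tot <- sum(ea)
  ebgm <- sweep(sweep(ea * n_tot, 2, row_g, "/"), 1, col_j, "/")
  if (nrow(config$drugs) == 1) ebgm[] <- NA_real_
  tibble(
    drug = rep(config$drugs$drug, each = nrow(config$events)),
    pt = rep(config$events$pt, times = nrow(config$drugs)),
    soc = rep(config$events$soc, times = nrow(config$drugs)),
    q = as.vector(q),
    expected_a = as.vector(ea),
    expected_ebgm = as.vector(ebgm)
  )
}
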