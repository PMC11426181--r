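Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pharmacovigilance pipeline for FAERS-style spontaneous
    adverse event report data: ingestion of '$'-delimited quarterly ASCII
    tables (DEMO, DRUG, REAC, OUTC, THER), case deduplication across quarterly
    releases, primary-suspect cohort selection with drug-synonym
    normalisation, MedDRA-style preferred-term to system-organ-class mapping,
    2x2 contingency construction at the PT and SOC levels, and four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio with chi-squared, the BCPNN information component, and
    the empirical Bayes geometric mean as an unshrunken relative reporting
    ratio) with 95% intervals and standard signal criteria. A synthetic
    spontaneous-report generator with planted signals and analytic ground
    truth makes every stage testable without access to the FAERS download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
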