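#' Read a FAERS-style '$'-delimited ASCII table
#'
#' Parses one table of a FAERS quarterly data extract: a plain-text file whose
#' first line is a `$`-delimited header and whose remaining lines are
#' `$`-delimited records. The dialect has no quoting or escaping, so a literal
#' `$` inside a value is unsupported (and rejected by [write_faers_table()]).
#'
#' Column names are lowercased and passed through [faers_column_aliases()] so
#' that pre- and post-2014 header variants (e.g. `ISR` vs `PRIMARYID`) land on
#' one canonical set. Values are kept verbatim; empty fields become empty
#' strings, never `NA`.
#'
#' @param path Path to the ASCII file.
#' @param table_kind One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"THER"`.
#'   Stored as an attribute on the result; parsing itself is kind-agnostic.
#' @param strict If `TRUE`, a line whose field count differs from the header
#'   aborts the read. If `FALSE` (default), such lines are rejected with a
#'   warning that carries their line numbers, and parsing continues.
#' @param encoding File encoding, `"latin1"` (historical FAERS default) or
#'   `"UTF-8"`.
#' @return A tibble of character columns, one row per accepted record, with
#'   attributes `table_kind` and `n_rejected` (count of malformed lines).
#' @seealso [write_faers_table()], [assemble_quarter_bundle()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("primaryid$caseid$sex", "100$1$F"), f)
#' read_faers_table(f, "DEMO")
read_faers_table <- function(path, table_kind, strict = FALSE,
                             encoding = c("latin1", "UTF-8")) {
  encoding <- match.arg(encoding)
  table_kind <- match.arg(toupper(table_kind), faers_table_kinds)
  if (!file.exists(path)) {
    abort(paste0("FAERS table file does not exist: ", path))
  }
  con <- file(path, open = "r", encoding = encoding)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    abort(paste0("empty file (no header line): ", path))
  }
  header <- strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]
  header <- faers_column_aliases(tolower(trimws(header)))
  if (anyDuplicated(header)) {
    abort(paste0("duplicate column names in header of ", path))
  }
  body <- lines[-1L]
  # strsplit drops trailing empty fields; pad by splitting with a sentinel.
  parts <- strsplit(paste0(body, "$\x01"), "$", fixed = TRUE)
  nfield <- lengths(parts) - 1L
  ok <- nfield == length(header)
  if (any(!ok)) {
    bad_lines <- which(!ok) + 1L
    msg <- paste0(
      "rejected ", sum(!ok), " malformed line(s) in ", basename(path),
      " (field count != ", length(header), ") at line(s): ",
      paste(head(bad_lines, 10L), collapse = ", ")
    )
    if (strict) abort(msg)
    warn(msg)
  }
  parts <- parts[ok]
  if (length(parts) == 0L) {
    out <- as_tibble(setNames(
      rep(list(character(0)), length(header)), header
    ))
  } else {
    mat <- matrix(unlist(parts), ncol = length(header) + 1L, byrow = TRUE)
    out <- as_tibble(setNames(
      lapply(seq_along(header), function(j) mat[, j]), header
    ))
  }
  attr(out, "table_kind") <- table_kind
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Write a table in the FAERS '$'-delimited dialect
#'
#' Inverse of [read_faers_table()]: writes a header line followed by one
#' `$`-joined line per row. `NA` values are written as empty strings. Because
#' the dialect has no escaping, any value containing `$` is an error.
#'
#' @param x A data frame of character (or coercible) columns.
#' @param path Output file path.
#' @param encoding Output encoding; default `"latin1"` matches historical
#'   FAERS files.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path, encoding = c("latin1", "UTF-8")) {
  encoding <- match.arg(encoding)
  x <- as_tibble(x)
  cols <- lapply(x, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  })
  if (any(vapply(cols, function(col) any(grepl("$", col, fixed = TRUE)),
                 logical(1)))) {
    abort("values containing a literal '$' cannot be represented in the FAERS dialect")
  }
  lines <- c(
    paste(names(x), collapse = "$"),
    if (nrow(x) > 0) do.call(paste, c(cols, sep = "$"))
  )
  con <- file(path, open = "w", encoding = encoding)
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Canonicalise FAERS column names across format eras
#'
#' Maps known header variants onto one canonical lowercase name so that files
#' from before and after the 2014 FAERS format change parse identically
#' (`isr` -> `primaryid`, `case` -> `caseid`, `drugname` stays, `drug_name`
#' folds in, etc.).
#'
#' @param x Character vector of lowercase column names.
#' @return Character vector of the same length with aliases replaced.
#' @export
faers_column_aliases <- function(x) {
  aliases <- c(
    isr = "primaryid",
    "case" = "caseid",
    case_id = "caseid",
    drug_name = "drugname",
    drugnam = "drugname",
    gndr_cod = "sex",
    country = "reporter_country"
  )
  hit <- x %in% names(aliases)
  x[hit] <- unname(aliases[x[hit]])
  x
}

#' Assemble one quarter's tables into a bundle
#'
#' Joins the five per-quarter tables into a `quarter_bundle`, enforcing the
#' referential invariant that every `caseid` in a child table (DRUG, REAC,
#' OUTC, THER) also appears in DEMO. Orphan child rows — routine in real
#' spontaneous-report extracts — are dropped, and their count recorded.
#'
#' @param tables Named list with element `demo` (required) and optionally
#'   `drug`, `reac`, `outc`, `ther`, each a tibble as returned by
#'   [read_faers_table()]. Missing child tables become empty.
#' @param quarter_id Quarter label `"YYYYqQ"`, e.g. `"2015q3"`; the year must
#'   be 2004 or later.
#' @return A `quarter_bundle`: a list with elements `quarter_id`, `demo`,
#'   `drug`, `reac`, `outc`, `ther` and attribute `n_orphans`.
#' @export
assemble_quarter_bundle <- function(tables, quarter_id) {
  stopifnot(is.list(tables))
  names(tables) <- tolower(names(tables))
  if (!grepl("^[0-9]{4}q[1-4]$", quarter_id) ||
      as.integer(substr(quarter_id, 1, 4)) < 2004) {
    abort(paste0("invalid quarter_id (want 'YYYYqQ', year >= 2004): ", quarter_id))
  }
  if (is.null(tables$demo) || nrow(tables$demo) == 0L) {
    abort(paste0("bundle ", quarter_id, " has no DEMO table; DEMO is required"))
  }
  demo <- as_tibble(tables$demo)
  if (!"caseid" %in% names(demo)) {
    abort("DEMO table lacks a 'caseid' column")
  }
  case_ids <- unique(demo$caseid)
  n_orphans <- 0L
  child <- function(kind) {
    x <- tables[[kind]]
    if (is.null(x)) {
      return(tibble(primaryid = character(0), caseid = character(0)))
    }
    x <- as_tibble(x)
    if (nrow(x) > 0L && "caseid" %in% names(x)) {
      keep <- x$caseid %in% case_ids
      n_orphans <<- n_orphans + sum(!keep)
      x <- x[keep, , drop = FALSE]
    }
    x
  }
  bundle <- structure(
    list(
      quarter_id = quarter_id,
      demo = demo,
      drug = child("drug"),
      reac = child("reac"),
      outc = child("outc"),
      ther = child("ther")
    ),
    class = "quarter_bundle"
  )
  if (n_orphans > 0L) {
    inform(paste0(quarter_id, ": dropped ", n_orphans,
                  " orphan child-table row(s) with no DEMO case"))
  }
  attr(bundle, "n_orphans") <- n_orphans
  bundle
}

#' @export
print.quarter_bundle <- function(x, ...) {
  cat("<quarter_bundle ", x$quarter_id, ">\n", sep = "")
  for (k in c("demo", "drug", "reac", "outc", "ther")) {
    cat("  ", toupper(k), ": ", nrow(x[[k]]), " row(s)\n", sep = "")
  }
  invisible(x)
}

#' Read all quarterly bundles from a directory
#'
#' Reads every quarter found under `dir` using the file naming pattern of the
#' FAERS quarterly extracts and assembles each into a bundle.
#'
#' @param dir Directory containing per-quarter table files.
#' @param pattern Filename pattern with placeholders `{TABLE}` (uppercase
#'   table name), `{YY}` (two-digit year) and `{Q}` (quarter digit).
#' @param strict,encoding Passed to [read_faers_table()].
#' @return List of `quarter_bundle`s, sorted by quarter.
#' @export
read_quarter_bundles <- function(dir, pattern = "{TABLE}{YY}Q{Q}.txt",
                                 strict = FALSE, encoding = "latin1") {
  rx <- paste0(
    "^",
    gsub("\\{Q\\}", "([1-4])",
         gsub("\\{YY\\}", "([0-9]{2})",
              gsub("\\{TABLE\\}", "(DEMO|DRUG|REAC|OUTC|THER)",
                   gsub("([.\\^$+?()\\[\\]])", "\\\\\\1", pattern)))),
    "$"
  )
  files <- list.files(dir)
  m <- regmatches(files, regexec(rx, files))
  hits <- lengths(m) == 4L
  if (!any(hits)) {
    abort(paste0("no files matching pattern '", pattern, "' under ", dir))
  }
  info <- tibble(
    file = files[hits],
    table = vapply(m[hits], `[[`, "", 2L),
    yy = vapply(m[hits], `[[`, "", 3L),
    q = vapply(m[hits], `[[`, "", 4L)
  ) |>
    mutate(quarter_id = paste0(
      ifelse(as.integer(.data$yy) < 50, 2000L, 1900L) + as.integer(.data$yy),
      "q", .data$q
    ))
  quarters <- sort(unique(info$quarter_id))
  lapply(quarters, function(qid) {
    rows <- info[info$quarter_id == qid, ]
    tabs <- setNames(
      lapply(seq_len(nrow(rows)), function(i) {
        read_faers_table(file.path(dir, rows$file[i]), rows$table[i],
                         strict = strict, encoding = encoding)
      }),
      tolower(rows$table)
    )
    assemble_quarter_bundle(tabs, qid)
  })
}

#' Write quarterly bundles to a directory
#'
#' Writes each table of each bundle in the FAERS ASCII dialect using the same
#' filename pattern that [read_quarter_bundles()] reads, so generated data
#' round-trips through the on-disk format.
#'
#' @param bundles List of `quarter_bundle`s.
#' @param dir Output directory (created if absent).
#' @param pattern Filename pattern, as in [read_quarter_bundles()].
#' @return `dir`, invisibly.
#' @export
write_quarter_bundles <- function(bundles, dir, pattern = "{TABLE}{YY}Q{Q}.txt") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (b in bundles) {
    yy <- substr(b$quarter_id, 3, 4)
    q <- substr(b$quarter_id, 6, 6)
    for (k in c("demo", "drug", "reac", "outc", "ther")) {
      fname <- gsub("{TABLE}", toupper(k),
                    gsub("{YY}", yy, gsub("{Q}", q, pattern, fixed = TRUE),
                         fixed = TRUE), fixed = TRUE)
      write_faers_table(b[[k]], file.path(dir, fname))
    }
  }
  invisible(dir)
}
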