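#' Construct a term map (raw term -> PT, PT -> SOC)
#'
#' A term map standardises reported event terms to preferred terms (PTs) and
#' rolls each PT up to a single primary system organ class (SOC), mirroring
#' the PT/SOC levels of a MedDRA-style dictionary. The dictionary itself is
#' licensed and therefore an input, never shipped: supply the two mapping
#' tables, or use the closed vocabulary emitted by the synthetic generator.
#'
#' @param pt_to_soc Data frame with columns `pt`, `soc` (one primary SOC per
#'   PT), or a named character vector `PT -> SOC`.
#' @param raw_to_pt Optional data frame with columns `raw`, `pt` (or named
#'   character vector) correcting raw spellings to PTs.
#' @param version Optional dictionary version string, carried into output
#'   metadata.
#' @return An object of class `term_map`.
#' @export
term_map <- function(pt_to_soc, raw_to_pt = NULL, version = NA_character_) {
  as_lut <- function(x, from, to) {
    if (is.null(x)) return(character(0))
    if (is.character(x)) return(setNames(unname(x), str_norm(names(x))))
    setNames(x[[to]], str_norm(x[[from]]))
  }
  soc_lut <- as_lut(pt_to_soc, "pt", "soc")
  if (length(unique(soc_lut)) > 27) {
    warn("more than 27 distinct SOCs in pt_to_soc; MedDRA defines 27")
  }
  structure(
    list(
      pt_to_soc = soc_lut,
      raw_to_pt = as_lut(raw_to_pt, "raw", "pt"),
      version = version
    ),
    class = "term_map"
  )
}

#' @export
print.term_map <- function(x, ...) {
  cat("<term_map: ", length(x$pt_to_soc), " PT(s), ",
      length(unique(x$pt_to_soc)), " SOC(s)",
      if (!is.na(x$version)) paste0(", version ", x$version), ">\n", sep = "")
  invisible(x)
}

#' Read a term map from mapping files
#'
#' @param pt_soc_path Two-column TSV (`PT`, `SOC`), no header, `#` comments
#'   allowed.
#' @param raw_pt_path Optional two-column TSV (`raw term`, `PT`).
#' @param version Optional dictionary version string.
#' @return A `term_map`.
#' @export
read_term_map <- function(pt_soc_path, raw_pt_path = NULL,
                          version = NA_character_) {
  read2 <- function(path, cols) {
    as_tibble(read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                         quote = "", col.names = cols,
                         colClasses = "character", strip.white = TRUE))
  }
  term_map(
    pt_to_soc = read2(pt_soc_path, c("pt", "soc")),
    raw_to_pt = if (!is.null(raw_pt_path)) read2(raw_pt_path, c("raw", "pt")),
    version = version
  )
}

#' Standardise raw event terms to preferred terms
#'
#' Lookup is case-insensitive and whitespace-normalised. Terms absent from
#' the raw-term map pass through verbatim (uppercased); the pass-through
#' count is attached as attribute `n_passthrough`.
#'
#' @param raw_term Character vector of reported event terms.
#' @param tm A `term_map`.
#' @return Character vector of PTs.
#' @export
map_pt <- function(raw_term, tm) {
  key <- str_norm(raw_term)
  out <- if (length(tm$raw_to_pt)) unname(tm$raw_to_pt[key]) else
    rep(NA_character_, length(key))
  miss <- is.na(out)
  out[miss] <- key[miss]
  attr(out, "n_passthrough") <- sum(miss)
  out
}

#' Roll a preferred term up to its primary system organ class
#'
#' Multiaxial PTs are resolved by the mapping file's single primary SOC, so
#' SOC-level counts are additive over PTs. PTs absent from the map return
#' `"UNMAPPED"`, which is reported separately and never silently merged.
#'
#' @param pt Character vector of PTs.
#' @param tm A `term_map`.
#' @return Character vector of SOC names.
#' @export
roll_up_soc <- function(pt, tm) {
  out <- unname(tm$pt_to_soc[str_norm(pt)])
  out[is.na(out)] <- "UNMAPPED"
  out
}
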