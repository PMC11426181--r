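#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signal table
#'
#' Returns the statistics as a plain tibble (one row per term), dropping the
#' class and metadata attributes.
#'
#' @param x A `faers_signals` object from [signal_stats()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.faers_signals <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "faers_signals")
  attr(out, "meta") <- NULL
  as_tibble(out)
}

#' One-row summary of a signal table
#'
#' @param x A `faers_signals` object.
#' @param ... Unused.
#' @return Tibble with the number of terms, total pair count, and per-method
#'   signal counts.
#' @export
glance.faers_signals <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_pairs = sum(x$a),
    n_ror_signals = sum(x$ror_signal),
    n_prr_signals = sum(x$prr_signal),
    n_bcpnn_signals = sum(x$bcpnn_signal),
    n_mgps_signals = sum(x$mgps_signal),
    n_any_signal = sum(x$ror_signal | x$prr_signal | x$bcpnn_signal |
                         x$mgps_signal)
  )
}

#' Tidy a pipeline run
#'
#' @param x A `faers_run` from [run_faers_pipeline()].
#' @param level `"PT"` or `"SOC"`.
#' @param ... Unused.
#' @return The tidied signal table at the requested level.
#' @export
tidy.faers_run <- function(x, level = c("PT", "SOC"), ...) {
  level <- match.arg(level)
  s <- if (level == "PT") x$signals_pt else x$signals_soc
  if (is.null(s)) abort("no SOC-level results (run without a term map)")
  tidy(s)
}

#' @rdname tidy.faers_run
#' @export
glance.faers_run <- function(x, ...) {
  bind_cols(
    tibble(
      target = x$metadata$target,
      n_cases = nrow(x$cases),
      n_cohort = nrow(x$cohort)
    ),
    glance(x$signals_pt)
  )
}
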