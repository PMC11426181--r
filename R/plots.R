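#' Forest plot of reporting odds ratios
#'
#' Draws the classic pharmacovigilance forest plot: ROR point estimates with
#' 95% intervals on a log scale, terms ordered by report count, signal terms
#' highlighted.
#'
#' @param object A `faers_signals` object.
#' @param top_k Show at most this many terms (by report count).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.faers_signals <- function(object, top_k = 30, ...) {
  df <- rank_terms(object, by = "count", top_k = top_k) |>
    filter(!is.na(.data$ror)) |>
    mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_lo, xmax = .data$ror_hi), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$ror_signal), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
      name = "ROR signal"
    ) +
    ggplot2::labs(x = "Reporting odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of the most-reported event terms
#'
#' @param results A `faers_signals` object (PT level).
#' @param tm Optional [term_map()]: bars are coloured by SOC.
#' @param top_k Number of terms shown.
#' @return A ggplot object.
#' @export
plot_top_terms <- function(results, tm = NULL, top_k = 30) {
  df <- rank_terms(results, by = "count", top_k = top_k, tm = tm) |>
    mutate(term = factor(.data$term, levels = rev(.data$term)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$term))
  p <- if ("soc" %in% names(df)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$soc)) +
      ggplot2::labs(fill = "SOC")
  } else {
    p + ggplot2::geom_col(fill = "steelblue")
  }
  p + ggplot2::labs(x = "Number of reports", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of the time-to-onset distribution
#'
#' @param onset_summary Output of `summarize_cohort(cohort, "onset")`.
#' @return A ggplot object.
#' @export
plot_onset_distribution <- function(onset_summary) {
  lv <- c("<7", "7-28", "28-60", ">=60", "Unknown")
  df <- onset_summary |>
    mutate(label = factor(.data$label, levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$percent, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "Days from therapy start to event",
                  y = "Number of reports") +
    ggplot2::theme_minimal()
}
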