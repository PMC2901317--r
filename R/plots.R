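#' Plot the distribution of the maximum-rank-sum statistic
#'
#' Histogram of `max_rank_stat` over probe sets. Values piling up at the
#' number of arrays M mean the same probe had the (untied) top intensity in
#' every array — the signature of reproducible cross-species hybridization of
#' one conserved probe per set.
#'
#' @param object A `maxrs_fit` from [run_maxrs()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maxrs_fit <- function(object, bins = 30, ...) {
  m_arr <- length(object$arrays)
  ggplot2::ggplot(object$selection, ggplot2::aes(x = .data$max_rank_stat)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = m_arr, linetype = "dashed") +
    ggplot2::labs(
      x = "max rank sum / number of probes",
      y = "probe sets",
      title = "Cross-array consistency of the top-ranked probe",
      subtitle = sprintf(
        "dashed line: value %d = same probe ranked top in all %d arrays",
        m_arr, m_arr
      )
    )
}

#' Volcano plot of moderated t-test results
#'
#' Log2 fold change against -log10 p-value, coloured by the FDR call.
#'
#' @param object A `maxrs_de` from [moderated_t_test()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.maxrs_de <- function(object, ...) {
  df <- tidy(object)
  lev <- attr(object, "group_levels")
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$logfc, y = -log10(.data$p_value), colour = .data$de_call
    )
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", none = "grey70")
    ) +
    ggplot2::labs(
      x = sprintf("log2 fold change (%s vs %s)", lev[2], lev[1]),
      y = expression(-log[10] ~ "p-value"),
      colour = sprintf("FDR %.0f%%", 100 * attr(object, "alpha"))
    )
}
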