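#' MA plot of per-spot ratio records
#'
#' Scatter of M against A for one or more arrays; if the records carry a
#' `fit` column (added by [lowess_normalize()]) the subtracted dye-bias
#' curve is overlaid, which makes before/after normalization comparisons
#' immediate.
#'
#' @param records A ratio tibble from [compute_ratios()] or
#'   [lowess_normalize()].
#' @return A ggplot object, faceted by array.
#' @export
plot_ma <- function(records) {
  p <- ggplot2::ggplot(records, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$array_id)) +
    ggplot2::labs(x = "A (average log2 intensity)", y = "M (log2 ratio)") +
    ggplot2::theme_minimal()
  if ("fit" %in% names(records)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$fit),
                                colour = "red", linewidth = 0.6)
  }
  p
}
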