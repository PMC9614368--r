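#' Plot a cost-effectiveness acceptability curve
#'
#' @param ceac_df Data frame from [ceac()] (columns `wtp`, `probability`).
#' @param wtp_line Optional threshold to mark (GBP/QALY); `NA` to omit.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df, wtp_line = 30000) {
  p <- ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp,
                                             y = .data$probability)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.na(wtp_line))
    p <- p + ggplot2::geom_vline(xintercept = wtp_line, linetype = "dashed")
  p
}

#' Plot the incremental cost-effectiveness plane
#'
#' Scatter of PSA draws; draws within the willingness-to-pay threshold are
#' distinguished from those outside it.
#'
#' @param psa A `clz_psa` object.
#' @param wtp Willingness-to-pay threshold (GBP/QALY).
#' @param max_points Subsample size for plotting.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 30000, max_points = 5000) {
  r <- psa$results
  if (nrow(r) > max_points) r <- r[seq_len(max_points), ]
  r$within <- wtp * r$delta_qaly - r$delta_cost > 0
  ggplot2::ggplot(r, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost,
                                  colour = .data$within)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "darkgreen",
                                            `FALSE` = "firebrick"),
                                 name = sprintf("within %s/QALY",
                                                format(wtp, big.mark = ","))) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                  title = "Incremental cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot a one-way deterministic sensitivity analysis
#'
#' @param dsa_df Data frame from [one_way_dsa()].
#' @param wtp_line Threshold to mark (GBP/QALY); `NA` to omit.
#' @return A ggplot object.
#' @export
plot_dsa <- function(dsa_df, wtp_line = 30000) {
  p <- ggplot2::ggplot(dsa_df, ggplot2::aes(x = .data$value, y = .data$icer)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = unique(dsa_df$parameter), y = "ICER (GBP/QALY)",
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
  if (!is.na(wtp_line))
    p <- p + ggplot2::geom_hline(yintercept = wtp_line, linetype = "dashed")
  p
}
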