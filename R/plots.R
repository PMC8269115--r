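# ggplot2 displays for the main result types.

#' Plot a PCA embedding colored by cluster
#'
#' @param object An `lps_embed` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lps_embed <- function(object, ...) {
  d <- object$scores
  ve <- round(100 * object$var_explained[1:2], 1)
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  color = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                  y = paste0("PC2 (", ve[2], "%)"),
                  color = "cluster") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object An `lps_de` result.
#' @param alpha Adjusted-p highlight threshold.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lps_de <- function(object, alpha = 0.05, ...) {
  d <- mutate(object$table, sig = .data$p.adjusted < alpha)
  ggplot2::ggplot(d, ggplot2::aes(.data$log2_fc, -log10(.data$p.value),
                                  color = .data$sig)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = bquote(log[2] ~ "fold change (" * .(object$group_b) *
                               " / " * .(object$group_a) * ")"),
                  y = expression(-log[10] ~ "p"),
                  color = paste("adj p <", alpha)) +
    ggplot2::theme_minimal()
}

#' Funnel plot of a TF screen
#'
#' @param object An `lps_screen` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lps_screen <- function(object, ...) {
  f <- mutate(object$funnel,
              stage = factor(.data$stage, levels = rev(.data$stage)),
              label = purrr::map2_chr(.data$n, .data$n[which.max(.data$n)],
                                      format_funnel_count))
  ggplot2::ggplot(f, ggplot2::aes(.data$n, .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.05,
                       size = 3) +
    ggplot2::expand_limits(x = max(f$n) * 1.15) +
    ggplot2::labs(x = "transcription factors", y = NULL) +
    ggplot2::theme_minimal()
}

#' Copy-number profile of one sample
#'
#' Per-bin copy estimates with segment means overlaid.
#'
#' @param copy_bins Output of [coverage_to_copy()].
#' @param segments Output of [segment_copy_number()] for the same sample.
#' @return A ggplot, faceted by chromosome.
#' @export
plot_copy_profile <- function(copy_bins, segments) {
  ggplot2::ggplot(copy_bins,
                  ggplot2::aes((.data$start + .data$end) / 2e6,
                               .data$copies)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = .data$copies, yend = .data$copies),
      color = "firebrick", linewidth = 1
    ) +
    ggplot2::geom_hline(yintercept = 2, linetype = 2, color = "grey50") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "copies") +
    ggplot2::theme_minimal()
}
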