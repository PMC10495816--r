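# ggplot2 visualizations for the main result types.

#' Plot the log2 ratio distribution of a RefQuant fit
#'
#' Violin-style density of per-precursor log2 target/reference ratios by
#' sample, the standard accuracy readout for mixing designs.
#'
#' @param object A `refquant_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot refquant_fit
#' @export
autoplot.refquant_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_name,
                                  y = log2(.data$ratio))) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "log2(target / reference)",
                  title = "RefQuant ratio distributions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a count-based FDR curve
#'
#' @param object A `channel_fdr_curve` from [channel_fdr_curve()].
#' @param ... Unused.
#' @return A ggplot of FDR versus Channel.Q.Value cutoff (log-log), with the
#'   1% FDR line marked.
#' @method autoplot channel_fdr_curve
#' @export
autoplot.channel_fdr_curve <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$fdr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.01, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Channel.Q.Value cutoff", y = "count-based FDR",
                  title = paste0("Empty-channel FDR (", d$level[1], " level)")) +
    ggplot2::theme_minimal()
}

#' Plot per-row CV distributions
#'
#' @param object A `cv_summary` from [cv_per_row()].
#' @param ... Unused.
#' @return A ggplot histogram of CVs with the median marked.
#' @method autoplot cv_summary
#' @export
autoplot.cv_summary <- function(object, ...) {
  d <- as_tibble(object)
  med <- attr(object, "median_cv")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cv)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = med, linetype = "dashed") +
    ggplot2::labs(x = "CV (%)", y = "rows",
                  title = sprintf("CV distribution (median %.1f%%)", med)) +
    ggplot2::theme_minimal()
}

#' Plot completeness by abundance quartile
#'
#' @param completeness Output of [completeness_by_quartile()].
#' @return A ggplot bar chart, most abundant quartile first.
#' @export
plot_completeness <- function(completeness) {
  ggplot2::ggplot(completeness,
                  ggplot2::aes(x = factor(.data$quartile),
                               y = .data$completeness)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "abundance quartile (1 = most abundant)",
                  y = "completeness",
                  title = "Data completeness by ranked quartile") +
    ggplot2::theme_minimal()
}
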