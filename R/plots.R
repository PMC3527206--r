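#' Plot methods for methylome result objects
#'
#' `autoplot()` methods render the package's main result types with
#' ggplot2: a `window_track` as per-chromosome methylation profiles, a
#' `meth_state_bins` as the binned ratio histogram coloured by state, a
#' `diff_track` as per-window methylation differences with flagged windows
#' highlighted, and a `feature_meth` as category-level mean methylation
#' bars.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot-methods
#' @export
autoplot.window_track <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$mean_meth)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "position (Mb)", y = "mean methylation ratio") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.meth_state_bins <- function(object, ...) {
  h <- object$histogram
  h$state <- classify_methylation_state(
    pmin(pmax((h$bin_start + h$bin_end) / 2, 0), 1),
    object$t_low, object$t_high)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_start, y = .data$fraction,
                                  fill = .data$state)) +
    ggplot2::geom_col(width = h$bin_end - h$bin_start, just = 0) +
    ggplot2::labs(x = "methylation ratio", y = "fraction of CpGs",
                  fill = "state") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.diff_track <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$delta, colour = .data$flagged)) +
    ggplot2::geom_point(size = 0.4, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = -attr(object, "cutoff"),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "position (Mb)", y = "methylation difference",
                  colour = "hypomethylated") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.feature_meth <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$category, y = .data$mean_ratio)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "average methylation ratio") +
    ggplot2::theme_minimal()
}
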