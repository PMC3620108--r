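#' Per-shell probe histogram with SEM error bars
#'
#' The radial localization summary plot: mean probe share (or within-shell
#' percentage) per shell with SEM error bars, shell 1 = periphery on the left
#' through shell N = center on the right. An increasing profile indicates
#' interior localization; a decreasing one peripheral localization.
#'
#' @param summary Aggregated tibble from [aggregate_profiles()] (or a
#'   `nucshell_batch$summary`); may contain several groups, which are
#'   faceted.
#' @param statistic `"share"` (probe share of total, default) or `"within"`
#'   (within-shell probe percentage).
#' @return A ggplot object.
#' @export
plot_shell_profile <- function(summary, statistic = c("share", "within")) {
  statistic <- match.arg(statistic)
  ycol <- if (statistic == "share") "mean_share_probe" else "mean_pct_probe"
  scol <- if (statistic == "share") "sem_share_probe" else "sem_pct_probe"
  ylab <- if (statistic == "share") "% probe signal (share of total)" else
    "% probe within shell"
  p <- ggplot(summary, aes(x = factor(.data$shell), y = .data[[ycol]])) +
    geom_col(fill = "firebrick", width = 0.75) +
    geom_errorbar(aes(ymin = .data[[ycol]] - .data[[scol]],
                      ymax = .data[[ycol]] + .data[[scol]]),
                  width = 0.25) +
    labs(x = "shell (1 = periphery, N = center)", y = ylab) +
    theme_bw()
  if ("group" %in% names(summary) && length(unique(summary$group)) > 1) {
    p <- p + facet_wrap(~group)
  }
  p
}

#' @rdname plot_shell_profile
#' @param object A `nucshell_batch`.
#' @param ... Passed to [plot_shell_profile()].
#' @export
autoplot.nucshell_batch <- function(object, ...) {
  if (is.null(object$summary)) abort("batch has no successful images to plot")
  plot_shell_profile(object$summary, ...)
}
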