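# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the cost-range selection criteria
#'
#' Shows, for each candidate cost, the small-worldness of the group-mean
#' network and which criteria passed; the selected contiguous range is
#' shaded.
#'
#' @param object a [select_cost_range()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cost_range <- function(object, ...) {
  d <- object$detail
  sel <- range(object$costs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cost, y = .data$sw)) +
    ggplot2::annotate("rect", xmin = sel[1], xmax = sel[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$pass), na.rm = TRUE) +
    ggplot2::labs(x = "cost (edge density)",
                  y = "small-worldness (group mean network)",
                  colour = "criteria pass",
                  title = sprintf("%s cost-range selection", object$modality)) +
    ggplot2::theme_minimal()
}

#' Plot a metric across the cost sweep
#'
#' @param data tibble with columns `cost`, `value` and optionally `group`.
#' @param ylab axis label for the metric.
#' @return a ggplot.
#' @export
plot_cost_profile <- function(data, ylab = "metric") {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$cost, y = .data$value))
  if ("group" %in% names(data)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$group))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "cost (edge density)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot individual structure-function coupling by group
#'
#' @param indiv tibble from [individual_coupling()] with a `group` column
#'   (join the cohort table first if needed).
#' @return a ggplot.
#' @export
plot_coupling <- function(indiv) {
  stopifnot("group" %in% names(indiv))
  ggplot2::ggplot(indiv, ggplot2::aes(x = .data$group, y = .data$r)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = "SC-FC coupling (Pearson r)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
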