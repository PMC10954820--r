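#' Plot the ALPS index by glycemic group
#'
#' Boxplots of the (measured or true) ALPS index across the NGM,
#' Pre-DM and T2DM groups, with individual subjects overlaid.
#'
#' @param data cohort tibble with `alps` and `group` columns.
#' @param outcome column to plot.
#' @return A ggplot object.
#' @export
plot_alps_groups <- function(data, outcome = "alps") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group,
                                     y = .data[[outcome]],
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.12, size = 1, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "ALPS index") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot the ALPS index against HOMA-IR
#'
#' Scatter plot with a linear fit and its confidence band, mirroring a
#' correlation figure for the merged Pre-DM and T2DM subjects.
#'
#' @param data cohort tibble with `alps` and `homa_ir` columns.
#' @param groups groups to include; defaults to Pre-DM and T2DM.
#' @return A ggplot object.
#' @export
plot_alps_homair <- function(data, groups = c("Pre-DM", "T2DM")) {
  d <- data[data$group %in% groups, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$homa_ir, y = .data$alps)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, color = "steelblue") +
    ggplot2::labs(x = "HOMA-IR", y = "ALPS index", color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname alps_group_comparison
#' @param object an `alps_glm` (autoplot method) with the original data
#'   attached via `data`.
#' @param data cohort tibble used to fit the comparison.
#' @export
autoplot.alps_glm <- function(object, data, ...) {
  plot_alps_groups(data, outcome = object$outcome)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
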