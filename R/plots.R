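# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_histogram geom_tile
#'   geom_point labs scale_fill_gradient2 facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' @export
autoplot.autoencoder <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$epoch, y = .data$mse)) +
    geom_line() +
    labs(x = "epoch", y = "reconstruction MSE",
      title = sprintf("autoencoder d = %d", object$d)) +
    theme_minimal()
}

#' @export
autoplot.consensus_result <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$agreement)) +
    geom_histogram(binwidth = 1 / length(attr(object, "partitions")),
      boundary = 0) +
    labs(x = "per-subject agreement fraction", y = "subjects",
      title = "consensus agreement") +
    theme_minimal()
}

#' @export
autoplot.robustness_report <- function(object, ...) {
  ggplot(tidy(object),
    aes(x = .data$iteration, y = .data$robustness,
      group = .data$members, colour = .data$members)) +
    geom_line() + geom_point() +
    ggplot2::geom_hline(yintercept = object$delta, linetype = "dashed") +
    labs(x = "merge iteration", y = "robustness index",
      colour = "cluster", title = "cluster robustness trajectory") +
    theme_minimal()
}

#' Plot an axial slice of a voxelwise statistic map
#'
#' @param glm a `voxel_glm` (or any tibble with `i`, `j`, `k` and the
#'   statistic column).
#' @param slice axial slice index (`k`); default the middle slice.
#' @param statistic column to plot (default `"t"`).
#' @return A ggplot object.
#' @export
plot_voxel_map <- function(glm, slice = NULL, statistic = "t") {
  tab <- if (inherits(glm, "voxel_glm")) glm$table else as_tibble(glm)
  if (is.null(slice)) slice <- round(stats::median(tab$k))
  dat <- tab[tab$k == slice, , drop = FALSE]
  ggplot(dat, aes(x = .data$i, y = .data$j,
    fill = .data[[statistic]])) +
    geom_tile() +
    scale_fill_gradient2() +
    labs(title = sprintf("%s map, axial slice k = %d", statistic, slice)) +
    theme_minimal()
}
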