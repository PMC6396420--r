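#' Plot a fetal-fraction profile
#'
#' Two aligned panels: the fetal- and shared-labelled fragment-length
#' distributions (the fetal mode sits near 140 bp, the maternal near
#' 166 bp), and the per-length fetal fraction with the total fraction as a
#' reference line.
#'
#' @param object A `nipgeno_ff_profile`.
#' @param tlen_range Length window to display.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nipgeno_ff_profile <- function(object, tlen_range = c(80L, 260L),
                                        ...) {
  tab <- filter(object$table, .data$tlen >= tlen_range[1L],
                .data$tlen <= tlen_range[2L])
  long <- tidyr::pivot_longer(
    select(tab, "tlen", "count_fetal", "count_shared"),
    cols = c("count_fetal", "count_shared"),
    names_to = "origin", values_to = "count"
  ) |>
    mutate(origin = if_else(.data$origin == "count_fetal",
                            "fetal-labelled", "shared-labelled"))
  p1 <- ggplot2::ggplot(long, ggplot2::aes(.data$tlen, .data$count,
                                           colour = .data$origin)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "fragments", colour = NULL) +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(tab, ggplot2::aes(.data$tlen, .data$ff)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$total_ff, linetype = "dashed") +
    ggplot2::labs(x = "template length (bp)", y = "fetal fraction") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, ncol = 1L)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of the accuracy grid
#'
#' Accuracy per (fetal fraction, depth) cell, one facet per site category —
#' the standard view of how prediction quality depends on the two sequencing
#' settings.
#'
#' @param grid Tibble from [grid_experiment()].
#' @return A ggplot object.
#' @export
plot_accuracy_grid <- function(grid) {
  ggplot2::ggplot(grid,
                  ggplot2::aes(factor(.data$depth), factor(.data$ff),
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$accuracy)), size = 3) +
    ggplot2::facet_wrap(~.data$category) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "median depth", y = "fetal fraction",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}
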