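# ggplot2 visualisations: rank maps, selections, protection summaries,
# overlap classes, and scenario ordinations.

#' @export
autoplot.rank_result <- function(object, grid = NULL, ...) {
  n <- length(object$rank)
  nrow_g <- if (!is.null(grid)) grid$nrow else round(sqrt(n))
  df <- tibble::tibble(cell = seq_len(n), rank = object$rank,
                       row = cell_row(seq_len(n), nrow_g),
                       col = cell_col(seq_len(n), nrow_g))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$rank)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  name = "priority\nrank") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Priority rank map (rule: %s)",
                                  object$meta$rule)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.protection_report <- function(object, grouping = "kingdom", ...) {
  df <- dplyr::filter(object$by_group, .data$grouping == !!grouping)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$spi)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$spi, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Species Protection Index (%)",
                  subtitle = sprintf("dashed: overall SPI %.1f%%", object$spi)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scenario_ordination <- function(object, ...) {
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$axis1, y = .data$axis2,
                               label = .data$scenario)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "NMDS axis 1", y = "NMDS axis 2",
                  title = sprintf("Scenario ordination (k = %d, stress = %.2f)",
                                  object$k, object$stress)) +
    ggplot2::theme_minimal()
}

#' Map overlap classes across scenario selections
#'
#' @param overlap Result of [overlap_classes()].
#' @param grid A [grid_def()] for the shared grid.
#' @return A ggplot object.
#' @export
plot_overlap <- function(overlap, grid) {
  cls <- overlap$class
  df <- tibble::tibble(cell = seq_along(cls), class = cls,
                       row = cell_row(seq_along(cls), grid$nrow),
                       col = cell_col(seq_along(cls), grid$nrow))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(No = "grey90", Some = "khaki2", Most = "orange2",
                 All = "firebrick"),
      na.value = "white", name = "scenarios") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, title = "Overlap of scenario selections") +
    ggplot2::theme_minimal()
}
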