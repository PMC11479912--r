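#' Plot a structure as a 2D projection
#'
#' Atoms are projected onto a coordinate plane and coloured by segment,
#' with main-chain atoms drawn larger; a quick visual check of segment
#' placement and perturbation level.
#'
#' @param object A [tcr_structure()].
#' @param plane Which coordinate plane to project on (`"xy"`, `"xz"`,
#'   `"yz"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcr_structure <- function(object, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[ax[1]]],
                                       y = .data[[ax[2]]],
                                       colour = .data$segment,
                                       size = .data$is_main_chain)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 1.8, `FALSE` = 0.8),
                               guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(ax[1], "(A)"), y = paste(ax[2], "(A)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a voxel grid channel as a max-intensity projection
#'
#' @param object A `voxel_grid` from [voxelize()].
#' @param channel Channel index (1-8) to display; defaults to the first
#'   (element) channel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_grid <- function(object, channel = 1L, ...) {
  proj <- apply(object$grid[, , , channel], c(1, 2), max)
  df <- expand.grid(x = seq_len(nrow(proj)), y = seq_len(ncol(proj)))
  df$value <- as.vector(proj)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (voxel)", y = "y (voxel)",
                  fill = sprintf("ch %d", channel)) +
    ggplot2::theme_minimal()
}
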