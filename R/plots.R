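#' Plot a density map
#'
#' Raster plot of the binarization-density surface on its native 0--255
#' scale, row 1 at the top so the plot matches the image orientation.
#'
#' @param object A [density_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_map <- function(object, ...) {
  v <- object$values
  df <- tibble::tibble(
    row = rep(seq_len(nrow(v)), times = ncol(v)),
    col = rep(seq_len(ncol(v)), each = nrow(v)),
    density = as.vector(v)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "density")
}

#' Plot a day-0-normalized invasion kinetics series
#'
#' One line per sample: relative size (day 0 = 1) against assay day.
#'
#' @param object An `assay_series` from [relative_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assay_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$day, .data$relative_size,
                                       colour = .data$label,
                                       group = .data$label)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day", y = "relative size (day 0 = 1)",
                  colour = "sample")
}

#' Perspective surface plot of a density map
#'
#' Base-graphics `persp` view of the density surface — the spheroid's
#' "footprint". The surface is downsampled to one vertex per tile for
#' legibility.
#'
#' @param map A [density_map()].
#' @param theta,phi Viewing angles passed to [graphics::persp()].
#' @param ... Further arguments to [graphics::persp()].
#' @return Invisibly, the perspective transformation matrix.
#' @export
plot_density_surface <- function(map, theta = 30, phi = 30, ...) {
  v <- map$values
  ts <- map$tile_size
  ri <- seq(1L, nrow(v), by = ts)
  ci <- seq(1L, ncol(v), by = ts)
  z <- v[ri, ci, drop = FALSE]
  graphics::persp(x = ri, y = ci, z = z, zlim = c(0, 255),
                  theta = theta, phi = phi, expand = 0.6,
                  xlab = "row", ylab = "col", zlab = "density", ...)
}
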