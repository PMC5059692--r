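#' Combine region masks into an overlay
#'
#' The three regions typically overlap (for a compact spheroid the periphery
#' ring sits inside the halo); the overlay is their pixel-wise union and is
#' the binary image that density quantification consumes.
#'
#' @param core,halo,periphery Logical masks of identical shape (`halo` may be
#'   a [extract_halo()] result, in which case its `$mask` is used).
#' @return A logical overlay mask (see [binary_mask()]).
#' @export
combine_overlay <- function(core, halo, periphery) {
  core <- as_mask(core); halo <- as_mask(halo); periphery <- as_mask(periphery)
  if (!identical(dim(core), dim(halo)) || !identical(dim(core), dim(periphery))) {
    abort("core, halo and periphery masks must have identical dimensions")
  }
  binary_mask(core | halo | periphery, "overlay")
}

#' Tile-averaged binarization density map
#'
#' Splits the binary overlay into `tile_size` x `tile_size` pixel sub-images
#' and assigns each tile the average of its binarized values stretched to
#' 0--255 (foreground = 255, background = 0): a fully covered tile scores
#' 255, an empty one 0, a half-covered one 127.5. Tiles at the right/bottom
#' edge that are cut by the frame are averaged over their actual pixel count.
#' The per-tile values are expanded back to full resolution (every pixel of a
#' tile carries the tile value) and adjacent tiles are then averaged with a
#' Gaussian filter of `smoothing_sigma` pixels, yielding a smooth density
#' surface; values are clipped to \[0, 255\].
#'
#' @param overlay Logical overlay mask from [combine_overlay()] (any logical
#'   matrix works).
#' @param tile_size Tile edge length in pixels; default 16.
#' @param smoothing_sigma Gaussian sigma (pixels) for the tile-averaging
#'   smoothing step; defaults to `tile_size`. Use 0 to disable smoothing.
#' @return A `density_map`: list with `values` (numeric matrix in
#'   \[0, 255\], same shape as the overlay), `tile_size` and
#'   `smoothing_sigma`.
#' @export
density_map <- function(overlay, tile_size = 16L, smoothing_sigma = tile_size) {
  m <- as_mask(overlay)
  tile_size <- as.integer(tile_size)
  if (tile_size < 1L || tile_size > nrow(m) || tile_size > ncol(m)) {
    abort("`tile_size` must be a positive integer no larger than either image dimension")
  }
  if (smoothing_sigma < 0) abort("`smoothing_sigma` must be non-negative")

  ri <- ceiling(seq_len(nrow(m)) / tile_size)
  ci <- ceiling(seq_len(ncol(m)) / tile_size)
  sums <- rowsum(m * 255, ri, reorder = TRUE)
  sums <- t(rowsum(t(sums), ci, reorder = TRUE))
  cnts <- tabulate(ri) %o% tabulate(ci)
  tiles <- sums / cnts
  vals <- tiles[ri, ci, drop = FALSE]
  dimnames(vals) <- NULL
  if (smoothing_sigma > 0) vals <- clip255(gaussian_blur(vals, smoothing_sigma))
  structure(list(values = vals, tile_size = tile_size,
                 smoothing_sigma = smoothing_sigma),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d px, tiles %d px, smoothing sigma %g, range [%.1f, %.1f]\n",
              nrow(x$values), ncol(x$values), x$tile_size, x$smoothing_sigma,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Integrate a density map into a size measure
#'
#' The integral (plain sum) of the density map over the whole frame is the
#' pipeline's measure of spheroid size-and-aggressiveness. Its units
#' (density x pixels) are arbitrary but cancel when a time series is
#' normalized to day 0 by [relative_series()].
#'
#' @param map A [density_map()] (or a bare numeric matrix of densities).
#' @return A single non-negative number, at most `255 * H * W`.
#' @export
integrate_density <- function(map) {
  v <- if (inherits(map, "density_map")) map$values else map
  sum(v)
}

#' Normalize a measurement series to day 0
#'
#' Spheroids cannot be fabricated at identical initial sizes, so sizes are
#' only comparable across samples after each sample is expressed relative to
#' its own day-0 measurement: `relative_size = integrated_density[day] /
#' integrated_density[day 0]`, making day 0 exactly 1. Static structures
#' recorded at day 0 (collagen impurities, extraneous cells) contribute to
#' every day's integral and are largely cancelled by the ratio.
#'
#' @param measurements A data frame with columns `day` and
#'   `integrated_density`, and optionally `label` (multiple samples are
#'   normalized independently per label). Typically rows from
#'   [measure_spheroid()].
#' @return An `assay_series` tibble: the input plus a `relative_size` column,
#'   ordered by day within label.
#' @export
relative_series <- function(measurements) {
  df <- tibble::as_tibble(measurements)
  if (!all(c("day", "integrated_density") %in% names(df))) {
    abort("`measurements` needs columns `day` and `integrated_density`")
  }
  if (!("label" %in% names(df))) df$label <- "sample"
  out <- df |>
    dplyr::group_by(.data$label) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      d0 <- g$integrated_density[g$day == 0]
      if (length(d0) != 1L) {
        abort(sprintf("sample '%s' must have exactly one day-0 measurement", key$label))
      }
      if (d0 <= 0) {
        abort(sprintf("sample '%s' has a zero day-0 integrated density; cannot normalize", key$label))
      }
      g$relative_size <- g$integrated_density / d0
      g
    }) |>
    dplyr::ungroup()
  class(out) <- c("assay_series", class(out))
  out
}

#' Full single-image quantification
#'
#' Runs the complete pipeline on one micrograph — background-subtracted core
#' extraction, watershed halo on the original image, Canny periphery,
#' overlay, density map — and returns all intermediate artifacts plus a
#' one-row measurement table. [measure_spheroid()] is the data-frame-first
#' shorthand that returns just the measurement row.
#'
#' @param img A [micrograph()] or numeric matrix in \[0, 255\].
#' @param config A [spherodens_config()].
#' @param label,day Identifiers stamped into the measurement row (label
#'   defaults to the micrograph's own label).
#' @return `analyze_micrograph()`: a `spheroid_analysis` list with `core`,
#'   `halo` (a `halo_result` or `NULL` when no core was found), `periphery`,
#'   `overlay`, `density` (a [density_map()]) and `measurement` (one-row
#'   tibble with `label`, `day`, `integrated_density`, `halo_area_px`,
#'   `halo_area_um2`, `config_hash`).
#' @export
analyze_micrograph <- function(img, config = spherodens_config(),
                               label = NULL, day = NA_integer_) {
  if (is.null(label)) {
    label <- if (inherits(img, "micrograph")) img$label else ""
  }
  core <- extract_core(img, config$criteria, config$preprocess)
  halo <- if (any(core)) {
    extract_halo(img, core, levels = config$halo_levels)
  } else NULL
  periphery <- extract_periphery(img, config$canny, config$preprocess)
  halo_mask <- if (is.null(halo)) core else halo$mask
  overlay <- combine_overlay(core, halo_mask, periphery)
  dmap <- density_map(overlay, config$tile_size, config$smoothing_sigma)
  measurement <- tibble::tibble(
    label = label, day = day,
    integrated_density = integrate_density(dmap),
    halo_area_px = if (is.null(halo)) 0L else halo$area_px,
    halo_area_um2 = if (is.null(halo)) NA_real_ else halo$area_um2,
    config_hash = config_hash(config)
  )
  structure(
    list(core = core, halo = halo, periphery = periphery, overlay = overlay,
         density = dmap, measurement = measurement),
    class = "spheroid_analysis"
  )
}

#' @rdname analyze_micrograph
#' @export
measure_spheroid <- function(img, config = spherodens_config(),
                             label = NULL, day = NA_integer_) {
  analyze_micrograph(img, config, label = label, day = day)$measurement
}

#' @export
print.spheroid_analysis <- function(x, ...) {
  m <- x$measurement
  cat(sprintf("<spheroid_analysis> label '%s' day %s\n", m$label, m$day))
  cat(sprintf("  core %d px | halo %s px | periphery %d edge px | integrated density %.1f\n",
              sum(x$core),
              if (is.null(x$halo)) "0" else format(x$halo$area_px),
              sum(x$periphery), m$integrated_density))
  invisible(x)
}

#' Tidiers for single-image analyses
#'
#' `tidy()` returns one row per segmented region with its pixel area and
#' area fraction; `glance()` returns the one-row measurement table.
#'
#' @param x A `spheroid_analysis` from [analyze_micrograph()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spheroid_analysis <- function(x, ...) {
  npx <- length(x$core)
  regions <- list(core = x$core,
                  halo = if (is.null(x$halo)) x$core else x$halo$mask,
                  periphery = x$periphery, overlay = x$overlay)
  tibble::tibble(
    region = names(regions),
    area_px = vapply(regions, sum, integer(1)),
    area_fraction = vapply(regions, sum, integer(1)) / npx
  )
}

#' @rdname tidy.spheroid_analysis
#' @export
glance.spheroid_analysis <- function(x, ...) x$measurement
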