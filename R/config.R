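#' Whole-pipeline configuration
#'
#' Bundles the per-stage configurations plus the density-map parameters.
#' The config hash stamped into measurement records lets a results table be
#' matched unambiguously to the settings that produced it.
#'
#' @param preprocess A [preprocess_config()].
#' @param criteria A [plausibility_criteria()].
#' @param canny A [canny_config()].
#' @param halo_levels Number of watershed flooding steps (see
#'   [extract_halo()]); default 256, one per gray level.
#' @param tile_size Density-map tile edge in pixels; default 16.
#' @param smoothing_sigma Density-map smoothing sigma; defaults to
#'   `tile_size`.
#' @return A `spherodens_config` list.
#' @export
spherodens_config <- function(preprocess = preprocess_config(),
                              criteria = plausibility_criteria(),
                              canny = canny_config(),
                              halo_levels = 256L,
                              tile_size = 16L,
                              smoothing_sigma = tile_size) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(criteria, "plausibility_criteria"),
            inherits(canny, "canny_config"))
  halo_levels <- as.integer(halo_levels)
  if (halo_levels < 1L) abort("`halo_levels` must be a positive integer")
  structure(
    list(preprocess = preprocess, criteria = criteria, canny = canny,
         halo_levels = halo_levels, tile_size = as.integer(tile_size),
         smoothing_sigma = smoothing_sigma),
    class = "spherodens_config"
  )
}

config_hash <- function(config) rlang::hash(unclass_deep(config))

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Build a pipeline configuration from a YAML file or nested list
#'
#' Recognized keys mirror the individual constructors:
#' `preprocess.blur_sigma_fraction`, `preprocess.gamma`,
#' `preprocess.periphery_background_subtraction`, `core.min_area_fraction`,
#' `core.max_center_offset`, `core.min_solidity`, `halo.levels`,
#' `periphery.low`, `periphery.high`, `periphery.sigma`,
#' `density.tile_size`, `density.smoothing_sigma`. Missing keys take their
#' documented defaults.
#'
#' @param x Path to a YAML file, or a nested list with the sections above.
#' @return A [spherodens_config()].
#' @export
read_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) abort("config must be a YAML file path or a list")
  g <- function(section, key, default) cfg[[section]][[key]] %||% default
  pre <- preprocess_config(
    blur_sigma_fraction = g("preprocess", "blur_sigma_fraction", 0.125),
    gamma = g("preprocess", "gamma", 1),
    periphery_background_subtraction =
      g("preprocess", "periphery_background_subtraction", FALSE)
  )
  crit <- plausibility_criteria(
    min_area_fraction = g("core", "min_area_fraction", 0.001),
    max_center_offset_fraction = g("core", "max_center_offset", 0.5),
    min_solidity = g("core", "min_solidity", 0.7)
  )
  can <- canny_config(
    low_threshold = g("periphery", "low", NULL),
    high_threshold = g("periphery", "high", NULL),
    smoothing_sigma = g("periphery", "sigma", 1)
  )
  tile <- g("density", "tile_size", 16L)
  spherodens_config(
    preprocess = pre, criteria = crit, canny = can,
    halo_levels = g("halo", "levels", 256L),
    tile_size = tile,
    smoothing_sigma = g("density", "smoothing_sigma", tile)
  )
}
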