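#' Watershed flooding trace from a core seed
#'
#' Floods the image outward from the seed, level by level: the image's own
#' intensity range `[min, max]` is quantized into `levels` steps, and at
#' step k the flooded region is the seed plus every pixel 8-connected to it
#' through pixels of intensity at most `min + k * (max - min) / levels`
#' (dark-object polarity: low intensity floods first). Anchoring the level
#' grid to the image range rather than to the absolute 0--255 scale makes
#' the flooding — and hence the halo — exactly invariant under affine
#' illumination changes (a global offset or contrast gain maps every
#' flooding level along with every pixel, so the flooded sets are
#' unchanged). Flooding is done on the original, non-background-subtracted
#' image, because subtraction also compresses contrast and would blur the
#' boundary between spheroid and field border. The trace records the nested
#' mask sequence up to and including the first step at which the flood
#' touches the 1-pixel image border frame.
#'
#' @param img A [micrograph()] or numeric matrix in \[0, 255\] (the original
#'   image, without background subtraction).
#' @param seed Logical seed mask (normally the core from [extract_core()]).
#' @param levels Number of flooding steps across the image intensity range;
#'   the default 256 floods at sub-gray-level resolution, so on
#'   integer-valued images the flood effectively advances one gray level at
#'   a time.
#' @return A `watershed_trace`: list with `iterations` (masks; element 1 is
#'   the seed, subsequent elements the flooded region per step, ending at the
#'   first border-touching step) and `stop_index` (index into `iterations`,
#'   counting the seed as 0, of that first border-touching step; `NA` if the
#'   seed itself already touches the border).
#' @seealso [extract_halo()] for the halo this trace defines.
#' @export
watershed_trace <- function(img, seed, levels = 256L) {
  px <- as_pixels(img)
  seed <- as_mask(seed)
  check_seed(px, seed)
  fl <- cpp_flood_levels(px, seed)
  border <- border_frame(dim(px))
  if (any(seed & border)) {
    return(structure(list(iterations = list(seed), stop_index = NA_integer_),
                     class = "watershed_trace"))
  }
  g <- flood_grid(px, levels)
  stop_k <- flood_stop(fl, border, g)
  iters <- vector("list", stop_k + 1L)
  iters[[1L]] <- seed
  for (k in seq_len(stop_k)) iters[[k + 1L]] <- (fl <= g$t[k]) | seed
  structure(list(iterations = iters, stop_index = stop_k),
            class = "watershed_trace")
}

#' Extract the halo by seeded watershed with a border stop criterion
#'
#' Grows the core outward with the level-by-level flooding of
#' [watershed_trace()] until the flooded region first touches the image
#' border; the flooded region of the step *before* that one is the halo.
#' For a compact spheroid with a sharp rim the halo nearly coincides with
#' the core; for a smoothly spread-out spheroid the flood runs through the
#' dense surrounding region before escaping to the border, so the halo
#' recovers the dense area that global thresholding under-covers. The flood
#' tends to spill into darker background patches, which is accepted: the
#' segmentation is later averaged into a density map where such spill is
#' negligible.
#'
#' @inheritParams watershed_trace
#' @param core Logical core mask from [extract_core()]; must be non-empty.
#' @param microns_per_pixel Optional calibration override; taken from `img`
#'   when it is a calibrated [micrograph()].
#' @return A `halo_result`: list with `mask` (logical halo mask, a superset
#'   of the core), `area_px`, `area_um2` (`NA` when uncalibrated; otherwise
#'   `area_px * microns_per_pixel^2`), `stop_index`, and `degenerate` (`TRUE`
#'   when the core already touched the border, in which case the halo is the
#'   core itself).
#' @export
extract_halo <- function(img, core, levels = 256L, microns_per_pixel = NULL) {
  px <- as_pixels(img)
  core <- as_mask(core)
  check_seed(px, core)
  if (is.null(microns_per_pixel) && inherits(img, "micrograph")) {
    microns_per_pixel <- img$microns_per_pixel
  }
  border <- border_frame(dim(px))
  if (any(core & border)) {
    warning("core touches the image border; halo degenerates to the core",
            call. = FALSE)
    return(halo_result(core, microns_per_pixel, stop_index = NA_integer_,
                       degenerate = TRUE))
  }
  fl <- cpp_flood_levels(px, core)
  g <- flood_grid(px, levels)
  stop_k <- flood_stop(fl, border, g)
  halo <- if (stop_k == 1L) core else ((fl <= g$t[stop_k - 1L]) | core)
  halo_result(halo, microns_per_pixel, stop_index = stop_k, degenerate = FALSE)
}

halo_result <- function(mask, microns_per_pixel, stop_index, degenerate) {
  area_px <- sum(mask)
  structure(
    list(mask = binary_mask(mask, "halo"),
         area_px = area_px,
         area_um2 = if (is.null(microns_per_pixel)) NA_real_
                    else area_px * microns_per_pixel^2,
         stop_index = stop_index,
         degenerate = degenerate),
    class = "halo_result"
  )
}

#' @export
print.halo_result <- function(x, ...) {
  cat(sprintf("<halo_result> area %d px%s%s\n", x$area_px,
              if (is.na(x$area_um2)) "" else sprintf(" (%.1f um^2)", x$area_um2),
              if (x$degenerate) ", degenerate (core touched border)" else
                sprintf(", border reached at flood step %d", x$stop_index)))
  invisible(x)
}

# Flooding thresholds: the image intensity range quantized into `levels`
# equal steps (t_k = min + k * (max - min) / levels, k = 1..levels).
flood_grid <- function(px, levels) {
  levels <- as.integer(levels)
  if (levels < 1L) abort("`levels` must be a positive integer")
  rng <- range(px)
  list(t = rng[1] + seq_len(levels) * (rng[2] - rng[1]) / levels,
       levels = levels)
}

# First flooding step whose flooded set reaches the border: the smallest k
# with t_k >= the minimal flood level on the border frame.
flood_stop <- function(fl, border, g) {
  border_fl <- min(fl[border])
  k <- which(g$t >= border_fl)[1]
  if (is.na(k)) g$levels else max(1L, as.integer(k))
}

border_frame <- function(d) {
  b <- matrix(FALSE, d[1], d[2])
  b[1, ] <- TRUE; b[d[1], ] <- TRUE; b[, 1] <- TRUE; b[, d[2]] <- TRUE
  b
}

check_seed <- function(px, seed) {
  if (!identical(dim(px), dim(seed))) {
    abort("seed mask dimensions must match the image")
  }
  if (!any(seed)) abort("halo extraction requires a non-empty core seed")
  invisible(TRUE)
}
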