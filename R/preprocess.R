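#' Preprocessing configuration
#'
#' Controls the illumination-correcting background subtraction and the
#' optional gamma adjustment applied before segmentation.
#'
#' @param blur_sigma_fraction Sigma of the strong Gaussian blur used by
#'   [background_subtract()], expressed as a fraction of the smaller image
#'   dimension, in (0, 1]. The default 0.125 (sigma = min(H, W) / 8) makes
#'   the blur kernel span the spheroid core, so field-scale illumination
#'   gradients are flattened while individual cells survive.
#' @param gamma Positive exponent for [apply_gamma()]; 1 (default) leaves the
#'   image unchanged. Raising gamma restores contrast in over-bright,
#'   low-contrast acquisitions.
#' @param periphery_background_subtraction Should background subtraction also
#'   be applied before periphery (edge) extraction? Off by default: on
#'   normally exposed images it makes the detected periphery systematically
#'   too small, and it is only worthwhile under extreme gradients or
#'   under-exposure.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(blur_sigma_fraction = 0.125, gamma = 1,
                              periphery_background_subtraction = FALSE) {
  stopifnot(is.numeric(blur_sigma_fraction), length(blur_sigma_fraction) == 1L)
  if (!(blur_sigma_fraction > 0 && blur_sigma_fraction <= 1)) {
    abort("`blur_sigma_fraction` must lie in (0, 1]")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    abort("`gamma` must be a single positive number")
  }
  structure(
    list(blur_sigma_fraction = blur_sigma_fraction, gamma = gamma,
         periphery_background_subtraction = isTRUE(periphery_background_subtraction)),
    class = "preprocess_config"
  )
}

# Gaussian blur with replicated borders. Brush size follows the usual
# 2*ceiling(3*sigma)+1 support, capped so the kernel never exceeds the image.
gaussian_blur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- min(dim(px))
  if (size > cap) size <- if (cap %% 2L == 1L) cap else cap - 1L
  if (size < 3L) size <- 3L
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(px, brush, boundary = "replicate"))
}

#' Illumination-correcting background subtraction
#'
#' Estimates the illumination field as a strong Gaussian blur of the image
#' (the blur averages out cells and other small detail, leaving the
#' brightness gradient) and removes that field's deviation from the image's
#' average intensity: each output pixel is
#' `clip(img - (blur(img) - mean(img)), 0, 255)`.
#' A pixel under a darker-than-average field is brightened, one under a
#' brighter-than-average field is darkened, so a pure linear illumination
#' ramp flattens to a near-constant image (up to blur boundary effects)
#' while structures much smaller than the blur sigma are left intact. The
#' output mean equals the input mean up to clipping; a constant image is
#' returned unchanged.
#'
#' @param img A [micrograph()] or numeric matrix in \[0, 255\].
#' @param cfg A [preprocess_config()]; only `blur_sigma_fraction` is used.
#' @return The corrected image, same type as the input.
#' @export
background_subtract <- function(img, cfg = preprocess_config()) {
  px <- as_pixels(img)
  sigma <- cfg$blur_sigma_fraction * min(dim(px))
  field <- gaussian_blur(px, sigma)
  out <- clip255(px - (field - mean(px)))
  rewrap(img, out)
}

#' Gamma adjustment
#'
#' Applies the power-law mapping `255 * (img / 255) ^ gamma`. Endpoints 0 and
#' 255 are fixed and pixel ordering is preserved for any positive gamma;
#' `gamma = 1` is the identity.
#'
#' @inheritParams background_subtract
#' @param gamma Positive exponent.
#' @return The adjusted image, same type as the input.
#' @export
apply_gamma <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0) {
    abort("`gamma` must be a single positive number")
  }
  px <- as_pixels(img)
  rewrap(img, 255 * (px / 255)^gamma)
}
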