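#' Micrograph objects
#'
#' A `micrograph` is the canonical in-memory form of one bright-field image:
#' a numeric matrix of intensities on the 0--255 scale (row-major, origin at
#' the top-left corner, 1-based row/column indices), an optional spatial
#' calibration in microns per pixel, and a free-text label. All downstream
#' stages (background subtraction, core/halo/periphery segmentation, density
#' quantification) consume and produce this representation; intensities may
#' become real-valued after preprocessing but always stay within \[0, 255\].
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\], at least
#'   64 x 64 pixels (smaller fields carry too little context for the
#'   three-region segmentation to be meaningful).
#' @param microns_per_pixel Optional positive scalar giving the spatial
#'   calibration. Required only to report halo areas in square microns.
#' @param label Free-text sample/day identifier carried through to results.
#'
#' @return An object of class `micrograph`: a list with elements `pixels`,
#'   `microns_per_pixel` and `label`.
#' @examples
#' m <- micrograph(matrix(128, 64, 64), microns_per_pixel = 2.5, label = "s1-d0")
#' dim(m$pixels)
#' @export
micrograph <- function(pixels, microns_per_pixel = NULL, label = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 64L || ncol(pixels) < 64L) {
    abort("a micrograph must be at least 64 x 64 pixels")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("micrograph intensities must lie in [0, 255] with no missing values")
  }
  if (!is.null(microns_per_pixel)) {
    if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
        !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
      abort("`microns_per_pixel` must be a single positive number")
    }
  }
  structure(
    list(pixels = pixels, microns_per_pixel = microns_per_pixel,
         label = as.character(label)),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cal <- if (is.null(x$microns_per_pixel)) "uncalibrated"
         else sprintf("%.4g um/px", x$microns_per_pixel)
  cat(sprintf("<micrograph> %d x %d px, intensities [%.1f, %.1f], %s%s\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels),
              cal, if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

# Accept either a micrograph or a bare numeric matrix wherever an image is
# expected; toy grids in examples/tests are then plain matrices.
as_pixels <- function(img) {
  if (inherits(img, "micrograph")) return(img$pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  abort("expected a micrograph or a numeric matrix")
}

# Rewrap processed pixels, preserving calibration and label.
rewrap <- function(img, pixels) {
  if (inherits(img, "micrograph")) {
    img$pixels <- pixels
    img
  } else {
    pixels
  }
}

#' Read a micrograph from a raster file
#'
#' Reads TIFF (including 16-bit), PNG or JPEG and converts to the canonical
#' grayscale representation on the 0--255 scale. Multi-channel images are
#' collapsed by ITU-R BT.601 luminance weighting (0.299 R + 0.587 G +
#' 0.114 B); higher bit depths are rescaled linearly by their full dtype
#' range, so an 8-bit value of 128 and a 16-bit value of 32896 both map to
#' 128. Loading is deterministic: the same file always yields bit-identical
#' pixels.
#'
#' @param path Path to a decodable TIFF/PNG/JPEG file.
#' @param microns_per_pixel Optional spatial calibration (see [micrograph()]).
#' @param label Identifier for the sample; defaults to the file name.
#' @return A [micrograph()].
#' @export
load_micrograph <- function(path, microns_per_pixel = NULL,
                            label = basename(path)) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("cannot read micrograph: no such file '%s'", path))
  }
  arr <- tryCatch(
    EBImage::readImage(path),
    error = function(e) abort(sprintf("cannot decode '%s': %s", path,
                                      conditionMessage(e)))
  )
  dat <- EBImage::imageData(arr) # width x height [x channels], values in [0,1]
  nd <- dim(dat)
  if (length(nd) < 2L || nd[1] == 0L || nd[2] == 0L) {
    abort(sprintf("'%s' decodes to a zero-sized image", path))
  }
  if (length(nd) == 3L) {
    gray <- if (nd[3] >= 3L) {
      0.299 * dat[, , 1] + 0.587 * dat[, , 2] + 0.114 * dat[, , 3]
    } else {
      dat[, , 1]
    }
  } else {
    gray <- dat
  }
  # EBImage stores (x, y); transpose to row = y, col = x.
  px <- t(gray) * 255
  px[px < 0] <- 0; px[px > 255] <- 255
  micrograph(px, microns_per_pixel = microns_per_pixel, label = label)
}

#' Write a binary mask as a lossless 8-bit image
#'
#' Foreground pixels are written as 255 and background as 0. PNG and TIFF are
#' lossless, so a written mask reloads bit-exactly: reading the file with
#' [load_micrograph()] and thresholding at 127 reproduces the mask.
#'
#' @param mask Logical matrix (or a mask from a segmentation stage).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @export
save_mask <- function(mask, path) {
  m <- as_mask(mask)
  ok <- tryCatch({
    EBImage::writeImage(EBImage::Image(t(m) * 1), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    abort(sprintf("cannot write mask to '%s'", path))
  }
  invisible(path)
}

#' Write a micrograph as an 8-bit grayscale image
#'
#' Intensities are rounded to whole gray levels and written losslessly
#' (PNG/TIFF), so integer-valued micrographs — e.g. rendered synthetic
#' scenes — round-trip bit-exactly through [load_micrograph()].
#'
#' @param img A [micrograph()] or numeric matrix in \[0, 255\].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @export
save_micrograph <- function(img, path) {
  px <- round(as_pixels(img))
  ok <- tryCatch({
    EBImage::writeImage(EBImage::Image(t(px) / 255), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    abort(sprintf("cannot write micrograph to '%s'", path))
  }
  invisible(path)
}

#' Binary region masks
#'
#' Segmentation stages return logical matrices tagged with the kind of region
#' they delineate (`core`, `halo`, `periphery` or `overlay`). `as_mask()`
#' coerces any logical/numeric matrix to a plain logical matrix;
#' `binary_mask()` additionally attaches the region kind.
#'
#' @param x Logical or numeric matrix.
#' @param region_kind One of `"core"`, `"halo"`, `"periphery"`, `"overlay"`.
#' @return A logical matrix with attribute `region_kind`.
#' @export
binary_mask <- function(x, region_kind = c("core", "halo", "periphery", "overlay")) {
  region_kind <- match.arg(region_kind)
  m <- as_mask(x)
  attr(m, "region_kind") <- region_kind
  m
}

#' @rdname binary_mask
#' @export
as_mask <- function(x) {
  if (is.list(x) && !is.null(x$mask)) x <- x$mask
  if (!is.matrix(x)) abort("a mask must be a matrix")
  m <- x != 0
  attributes(m) <- list(dim = dim(x))
  m
}

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}
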