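#' Canny configuration for periphery extraction
#'
#' @param low_threshold,high_threshold Hysteresis thresholds on the Sobel
#'   gradient magnitude (same intensity units as the image). When `NULL`
#'   (default) they are derived per image: `high` is the Otsu threshold of
#'   the square-root-compressed gradient-magnitude histogram (mapped back
#'   to magnitude units) and `low = high / 2`. The square-root compression
#'   variance-stabilizes the histogram: a raw gradient histogram is
#'   dominated by the spheroid boundary's extreme magnitudes, which drags
#'   the Otsu split above the much weaker single-cell edges the periphery
#'   exists to capture. The rule is deterministic and config-overridable.
#' @param smoothing_sigma Sigma (pixels) of the Gaussian smoothing applied
#'   before gradient computation; default 1.
#' @return A `canny_config` list.
#' @export
canny_config <- function(low_threshold = NULL, high_threshold = NULL,
                         smoothing_sigma = 1) {
  if (!is.numeric(smoothing_sigma) || length(smoothing_sigma) != 1L ||
      smoothing_sigma <= 0) {
    abort("`smoothing_sigma` must be a single positive number")
  }
  if (!is.null(low_threshold) && !is.null(high_threshold) &&
      !(low_threshold < high_threshold)) {
    abort("`low_threshold` must be below `high_threshold`")
  }
  structure(
    list(low_threshold = low_threshold, high_threshold = high_threshold,
         smoothing_sigma = smoothing_sigma),
    class = "canny_config"
  )
}

#' Extract the periphery as a Canny edge map
#'
#' Scattered single cells that have invaded beyond the halo cannot be
#' segmented as one object, and counting them is unreliable in a 2-D
#' cross-section of a 3-D scene. Instead the periphery is represented by
#' image granularity: the more cells in an area, the more edges a Canny
#' detector finds there, so the local edge-pixel count is a monotone proxy
#' for local cell density. The edge map is computed over the whole frame;
#' overlap with core/halo is resolved later by the overlay union.
#'
#' Steps: optional background subtraction (only when
#' `pre$periphery_background_subtraction` is set — recommended only for
#' extreme gradients or severe under-exposure, since it shrinks the detected
#' periphery on normal images), Gaussian smoothing, Sobel gradients,
#' non-maximum suppression perpendicular to the edge, and hysteresis
#' thresholding (weak edges kept only when 8-connected to a strong edge).
#' A constant image yields an empty mask.
#'
#' @param img A [micrograph()] or numeric matrix in \[0, 255\].
#' @param cfg A [canny_config()].
#' @param pre A [preprocess_config()]; gamma, when not 1, is applied first.
#' @return A logical periphery mask (see [binary_mask()]).
#' @export
extract_periphery <- function(img, cfg = canny_config(),
                              pre = preprocess_config()) {
  px <- as_pixels(img)
  if (pre$gamma != 1) px <- 255 * (px / 255)^pre$gamma
  if (pre$periphery_background_subtraction) {
    px <- as_pixels(background_subtract(px, pre))
  }
  edges <- canny_edges(px, cfg)
  binary_mask(edges, "periphery")
}

canny_edges <- function(px, cfg) {
  sm <- gaussian_blur(px, cfg$smoothing_sigma)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dcol
  gx <- as.matrix(EBImage::filter2(sm, sx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(sm, t(sx), boundary = "replicate"))
  mag <- sqrt(gx^2 + gy^2)
  # floor well above FFT rounding residue on the 0-255 intensity scale
  if (max(mag) <= 1e-6) {
    return(matrix(FALSE, nrow(px), ncol(px)))
  }

  hi <- cfg$high_threshold
  lo <- cfg$low_threshold
  if (is.null(hi)) {
    # Otsu on the sqrt-compressed magnitudes, mapped back to magnitude units
    s <- sqrt(mag)
    hi <- tryCatch((otsu_threshold(s / max(s) * 255) / 255 * max(s))^2,
                   error = function(e) NULL)
    if (is.null(hi)) return(matrix(FALSE, nrow(px), ncol(px)))
  }
  if (is.null(lo)) lo <- hi / 2

  nms <- nonmax_suppress(mag, gx, gy)
  strong <- nms >= hi
  if (!any(strong)) return(matrix(FALSE, nrow(px), ncol(px)))
  weak <- nms >= lo
  # hysteresis: weak pixels reachable from a strong pixel through weak
  # pixels; minimax flood over the weak-mask indicator costs 0 exactly there
  fl <- cpp_flood_levels((!weak) * 1, strong)
  weak & (fl <= 0)
}

# Non-maximum suppression: keep a pixel only if its gradient magnitude is a
# local maximum along the gradient direction, quantized to 4 sectors.
nonmax_suppress <- function(mag, gx, gy) {
  H <- nrow(mag); W <- ncol(mag)
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  # sector 0: horizontal gradient (compare cols); 1: 45deg; 2: vertical; 3: 135deg
  sector <- integer(length(ang))
  sector[(ang < 22.5) | (ang >= 157.5)] <- 0L
  sector[ang >= 22.5 & ang < 67.5] <- 1L
  sector[ang >= 67.5 & ang < 112.5] <- 2L
  sector[ang >= 112.5 & ang < 157.5] <- 3L

  shift <- function(m, dr, dc) {
    out <- matrix(0, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  n1 <- matrix(0, H, W); n2 <- matrix(0, H, W)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    o <- offs[[as.character(s)]]
    sel <- sector == s
    a <- shift(mag, o[1], o[2]); b <- shift(mag, -o[1], -o[2])
    n1[sel] <- a[sel]; n2[sel] <- b[sel]
  }
  out <- mag
  out[mag < n1 | mag < n2] <- 0
  out
}
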