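#' Otsu threshold on the 0--255 scale
#'
#' Builds a 256-bin intensity histogram (bin k covers \[k, k+1) gray levels,
#' with 255 in the last bin) and returns the threshold `t` in 0..254 that
#' maximizes the between-class variance of the split into bins `<= t` versus
#' bins `> t`. Ties are resolved by averaging the tied candidates, so a
#' perfectly bimodal image gets the midpoint of the empty gap. The dark
#' ("cell") class of a bright-field image is `pixels <= t`.
#'
#' @param img A [micrograph()] or numeric matrix in \[0, 255\].
#' @return A single numeric threshold in \[0, 255\].
#' @export
otsu_threshold <- function(img) {
  px <- as_pixels(img)
  if (max(px) - min(px) < .Machine$double.eps * 255) {
    abort("cannot threshold a constant image: no intensity classes to separate")
  }
  bins <- pmin(floor(px), 255)
  counts <- tabulate(as.integer(bins) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)[1:255]
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  w1 <- 1 - w0
  # between-class variance; defined only where both classes are populated
  num <- (mu_t * w0 - mu[1:255])^2
  sigma_b <- ifelse(w0 > 0 & w1 > 0, num / (w0 * w1), -Inf)
  best <- which(sigma_b == max(sigma_b)) - 1L
  mean(best)
}

#' Shape-plausibility criteria for core candidates
#'
#' After thresholding, connected dark components are screened by shape before
#' one is accepted as the spheroid core: debris specks are small, spheroids
#' sit near the field center (one spheroid is embedded per well), and a core
#' is a near-convex blob.
#'
#' @param min_area_fraction Minimum component area as a fraction of the image
#'   area, in (0, 1). Default 0.001.
#' @param max_center_offset_fraction Maximum allowed distance of the
#'   component centroid from the image center, as a fraction of the image
#'   half-diagonal, in (0, 1]. Default 0.5.
#' @param min_solidity Minimum area / convex-hull-area ratio, in (0, 1].
#'   Default 0.7.
#' @return A `plausibility_criteria` list.
#' @export
plausibility_criteria <- function(min_area_fraction = 0.001,
                                  max_center_offset_fraction = 0.5,
                                  min_solidity = 0.7) {
  chk <- function(x, lo_open, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || x <= lo_open || x > hi) {
      abort(sprintf("`%s` must lie in (%g, %g]", nm, lo_open, hi))
    }
  }
  chk(min_area_fraction, 0, 1 - 1e-12, "min_area_fraction")
  chk(max_center_offset_fraction, 0, 1, "max_center_offset_fraction")
  chk(min_solidity, 0, 1, "min_solidity")
  structure(
    list(min_area_fraction = min_area_fraction,
         max_center_offset_fraction = max_center_offset_fraction,
         min_solidity = min_solidity),
    class = "plausibility_criteria"
  )
}

# Solidity of a pixel component: area over convex hull area. Hull area uses
# the shoelace formula with the discrete A + P/2 + 1 correction so a filled
# digital disk scores ~1.
component_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n < 3L) return(1)
  pts <- cbind(cols, rows)
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3L) return(1)
  nxt <- c(2:m, 1L)
  area <- abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
  perim <- sum(sqrt(rowSums((hp - hp[nxt, , drop = FALSE])^2)))
  hull_px <- area + perim / 2 + 1
  min(1, n / hull_px)
}

#' Extract the spheroid core
#'
#' Core segmentation pipeline: background subtraction (and gamma adjustment
#' when configured), Otsu thresholding, selection of the dark class (cells
#' are darker than background in bright-field), 8-connected component
#' labelling, shape-plausibility screening, selection of the best surviving
#' component (largest area, ties broken by centroid closest to the image
#' center) and interior hole filling — the downstream watershed needs a
#' solid seed. An empty mask is a legal result: a blank field, or one where
#' no component passes the screen, yields no core.
#'
#' @param img A [micrograph()] or numeric matrix in \[0, 255\] (the raw
#'   image; preprocessing is applied internally).
#' @param criteria A [plausibility_criteria()].
#' @param cfg A [preprocess_config()].
#' @return A logical core mask (see [binary_mask()]); a single connected
#'   component or empty.
#' @export
extract_core <- function(img, criteria = plausibility_criteria(),
                         cfg = preprocess_config()) {
  px <- as_pixels(img)
  if (cfg$gamma != 1) px <- 255 * (px / 255)^cfg$gamma
  sub <- as_pixels(background_subtract(px, cfg))
  empty <- binary_mask(matrix(FALSE, nrow(px), ncol(px)), "core")
  thr <- tryCatch(otsu_threshold(sub), error = function(e) NULL)
  if (is.null(thr)) return(empty)

  dark <- sub <= thr
  lab <- cpp_label8(dark)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)

  H <- nrow(px); W <- ncol(px)
  half_diag <- sqrt((H / 2)^2 + (W / 2)^2)
  min_area <- criteria$min_area_fraction * H * W
  ctr <- c((H + 1) / 2, (W + 1) / 2)

  idx <- which(lab > 0)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  labv <- lab[idx]
  areas <- tabulate(labv, nlab)
  cand <- which(areas >= min_area)
  if (!length(cand)) return(empty)

  best_lab <- 0L; best_area <- -1; best_off <- Inf
  for (l in cand) {
    sel <- labv == l
    r <- rows[sel]; cc <- cols[sel]
    off <- sqrt((mean(r) - ctr[1])^2 + (mean(cc) - ctr[2])^2) / half_diag
    if (off > criteria$max_center_offset_fraction) next
    if (component_solidity(r, cc) < criteria$min_solidity) next
    a <- areas[l]
    if (a > best_area || (a == best_area && off < best_off)) {
      best_lab <- l; best_area <- a; best_off <- off
    }
  }
  if (best_lab == 0L) return(empty)
  core <- lab == best_lab
  core <- as.matrix(EBImage::fillHull(core * 1)) != 0
  binary_mask(core, "core")
}
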