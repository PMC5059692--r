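#' Illumination models for synthetic scenes
#'
#' The five models emulate the acquisition conditions a bright-field
#' invasion assay actually meets: an even field (`flat`), a linear
#' brightness ramp across the field (`linear_gradient`), a shadow falling in
#' from one corner (`corner_shadow`, Gaussian falloff from the top-left
#' corner with spatial scale `scale * min(H, W)`), global under-exposure
#' (`underexposed`, a constant intensity offset subtracted everywhere) and
#' an over-bright, contrast-compressed acquisition (`bright_low_contrast`,
#' intensities pulled toward white by `out = 255 - (255 - in) * gain`).
#'
#' @param kind One of `"flat"`, `"linear_gradient"`, `"corner_shadow"`,
#'   `"underexposed"`, `"bright_low_contrast"`.
#' @param strength Gray levels of the gradient span / shadow depth
#'   (defaults 40 and 35).
#' @param offset Gray levels subtracted for `underexposed` (default 50).
#' @param gain Contrast gain in (0, 1\] for `bright_low_contrast`
#'   (default 0.45).
#' @param scale Shadow spatial scale as a fraction of min(H, W)
#'   (default 0.25).
#' @return An `illumination` list.
#' @export
illumination <- function(kind = c("flat", "linear_gradient", "corner_shadow",
                                  "underexposed", "bright_low_contrast"),
                         strength = NULL, offset = 50, gain = 0.45,
                         scale = 0.25) {
  kind <- match.arg(kind)
  strength <- strength %||% switch(kind, linear_gradient = 40, corner_shadow = 35, 0)
  if (gain <= 0 || gain > 1) abort("`gain` must lie in (0, 1]")
  structure(list(kind = kind, strength = strength, offset = offset,
                 gain = gain, scale = scale),
            class = "illumination")
}

apply_illumination <- function(px, ill) {
  H <- nrow(px); W <- ncol(px)
  switch(ill$kind,
    flat = px,
    linear_gradient = {
      ramp <- matrix(seq(-ill$strength / 2, ill$strength / 2, length.out = W),
                     H, W, byrow = TRUE)
      px + ramp
    },
    corner_shadow = {
      d2 <- outer((seq_len(H) - 1)^2, (seq_len(W) - 1)^2, `+`)
      tau <- ill$scale * min(H, W)
      px - ill$strength * exp(-d2 / (2 * tau^2))
    },
    underexposed = px - ill$offset,
    bright_low_contrast = 255 - (255 - px) * ill$gain
  )
}

#' Describe a synthetic spheroid scene
#'
#' Parameterizes a bright-field-like micrograph with exact ground truth: a
#' dense dark core disk, a radial intensity ramp standing in for the dense
#' escaping-cell ring around the core, scattered dark Gaussian-profiled
#' blobs standing in for single invading cells, an illumination model, and
#' additive camera noise. Defaults depict a compact spheroid: a 256 px
#' field, a 60 px core about 140 gray levels darker than the background,
#' and a sharp 6 px rim; widen `halo_width` to emulate a smoothly
#' spread-out, invasive spheroid.
#'
#' @param image_size Field edge length in pixels (square), at least 64.
#' @param core_radius Core disk radius in pixels.
#' @param core_intensity,background_intensity Gray levels in \[0, 255\];
#'   the core must be darker than the background (bright-field polarity).
#' @param halo_width Width in pixels of the linear intensity ramp from core
#'   to background level; small = sharp rim, large = diffuse spread-out rim.
#' @param n_peripheral_cells Number of scattered cell blobs.
#' @param cell_radius_range Min/max blob radius (pixels).
#' @param placement_ring Inner/outer radius of the annulus cells are placed
#'   in; default from just outside the rim to just inside the frame. An
#'   outer radius beyond the frame is allowed (cells may land partly outside
#'   the field, as real invaders do) and flagged in the ground truth.
#' @param cell_contrast Peak blob darkening in gray levels.
#' @param noise_sigma Additive Gaussian camera noise sigma in gray levels.
#'   The default 0.3 matches a well-exposed 8-bit bright-field acquisition,
#'   where per-pixel noise is a fraction of one gray level; raise it to
#'   emulate under-exposed, noisy acquisitions.
#' @param illum An [illumination()] model.
#' @param optical_blur_sigma Sigma of the mild Gaussian blur applied to the
#'   ideal geometry before illumination/noise, emulating optics. At the
#'   emulated scale (a low-magnification field downsampled to a 256 px
#'   frame, several microns per pixel) the microscope PSF is well below one
#'   pixel, so the default 0.5 provides antialiasing of the discrete
#'   geometry rather than a resolved blur.
#' @param seed Integer RNG seed; rendering is fully deterministic given the
#'   scene (a single seeded RNG stream drives cell placement and noise).
#' @return A `spheroid_scene` list.
#' @export
spheroid_scene <- function(image_size = 256L, core_radius = 60,
                           core_intensity = 60, background_intensity = 200,
                           halo_width = 6, n_peripheral_cells = 0L,
                           cell_radius_range = c(2, 4),
                           placement_ring = NULL, cell_contrast = 70,
                           noise_sigma = 0.3, illum = illumination("flat"),
                           optical_blur_sigma = 0.5, seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 64L) abort("`image_size` must be at least 64")
  if (!(core_intensity < background_intensity)) {
    abort("the core must be darker than the background")
  }
  if (core_radius <= 0 || halo_width < 0) {
    abort("`core_radius` must be positive and `halo_width` non-negative")
  }
  if (core_radius + halo_width >= image_size / 2 - 2) {
    abort("core plus rim does not fit inside the frame")
  }
  if (is.null(placement_ring)) {
    placement_ring <- c(core_radius + halo_width + 8, image_size / 2 - 8)
  }
  if (n_peripheral_cells > 0L && placement_ring[1] >= placement_ring[2]) {
    abort("`placement_ring` must satisfy inner < outer")
  }
  stopifnot(inherits(illum, "illumination"))
  structure(
    list(image_size = image_size, core_radius = core_radius,
         core_intensity = core_intensity,
         background_intensity = background_intensity,
         halo_width = halo_width,
         n_peripheral_cells = as.integer(n_peripheral_cells),
         cell_radius_range = cell_radius_range,
         placement_ring = placement_ring, cell_contrast = cell_contrast,
         noise_sigma = noise_sigma, illum = illum,
         optical_blur_sigma = optical_blur_sigma, seed = as.integer(seed),
         beyond_frame = placement_ring[2] > (image_size - 1) / 2),
    class = "spheroid_scene"
  )
}

with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Render a synthetic scene to a micrograph with ground truth
#'
#' Deterministic for a fixed scene (same seed, bit-identical pixels). The
#' render order is: ideal geometry (core disk, rim ramp, cell blobs), mild
#' optical blur, illumination model, additive camera noise, then clipping
#' to \[0, 255\] and rounding to whole gray levels — the output is an
#' integer-valued 8-bit frame, exactly what a camera delivers and what
#' loading a stored micrograph yields. Because the illumination model
#' consumes no randomness, the
#' same scene rendered under different illumination models carries the
#' identical noise field — exactly what a robustness experiment that
#' re-images one physical sample under varied lighting needs.
#'
#' @param scene A [spheroid_scene()].
#' @param microns_per_pixel Optional calibration stamped on the output.
#' @return A list with `image` (a [micrograph()]) and `truth`: `core`
#'   (logical mask of the ideal core disk), `dense` (core plus rim — the
#'   region the halo should recover), `cells` (tibble of blob centers:
#'   `row`, `col`, `radius`, `beyond_frame`).
#' @export
render_scene <- function(scene, microns_per_pixel = NULL) {
  n <- scene$image_size
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n) - ctr
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  r <- sqrt(rr^2 + cc^2)

  bg <- scene$background_intensity; co <- scene$core_intensity
  px <- matrix(bg, n, n)
  if (scene$halo_width > 0) {
    ramp <- r > scene$core_radius & r < scene$core_radius + scene$halo_width
    px[ramp] <- co + (bg - co) * (r[ramp] - scene$core_radius) / scene$halo_width
  }
  px[r <= scene$core_radius] <- co

  cells <- with_seed(scene$seed, {
    k <- scene$n_peripheral_cells
    if (k > 0L) {
      rad_pos <- runif(k, scene$placement_ring[1], scene$placement_ring[2])
      ang <- runif(k, 0, 2 * pi)
      tibble::tibble(
        row = ctr + rad_pos * sin(ang),
        col = ctr + rad_pos * cos(ang),
        radius = runif(k, scene$cell_radius_range[1], scene$cell_radius_range[2])
      )
    } else {
      tibble::tibble(row = numeric(), col = numeric(), radius = numeric())
    }
  })
  if (nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      px <- stamp_blob(px, cells$row[i], cells$col[i], cells$radius[i],
                       scene$cell_contrast)
    }
    cells$beyond_frame <- cells$row < 1 | cells$row > n |
      cells$col < 1 | cells$col > n
  } else {
    cells$beyond_frame <- logical()
  }

  if (scene$optical_blur_sigma > 0) {
    px <- gaussian_blur(px, scene$optical_blur_sigma)
  }
  px <- apply_illumination(px, scene$illum)
  if (scene$noise_sigma > 0) {
    noise <- with_seed(scene$seed + 1000003L,
                       matrix(rnorm(n * n, 0, scene$noise_sigma), n, n))
    px <- px + noise
  }
  px <- round(clip255(px))

  list(
    image = micrograph(px, microns_per_pixel = microns_per_pixel,
                       label = sprintf("synthetic-seed%d", scene$seed)),
    truth = list(core = r <= scene$core_radius,
                 dense = r <= scene$core_radius + scene$halo_width,
                 cells = cells)
  )
}

# Subtract a Gaussian-profiled dark blob, clipped at the frame. Gaussian
# profiles (rather than hard disks) give the edge detector realistic
# gradients.
stamp_blob <- function(px, row, col, radius, contrast) {
  n1 <- nrow(px); n2 <- ncol(px)
  s <- radius / 1.5
  ext <- ceiling(3 * s)
  rs <- max(1, floor(row - ext)):min(n1, ceiling(row + ext))
  cs <- max(1, floor(col - ext)):min(n2, ceiling(col + ext))
  if (!length(rs) || !length(cs)) return(px)
  d2 <- outer((rs - row)^2, (cs - col)^2, `+`)
  px[rs, cs] <- px[rs, cs] - contrast * exp(-d2 / (2 * s^2))
  px
}

#' Render a daily time series of a growing/invading scene
#'
#' Day 0 is the base scene; each subsequent day grows the core radius, adds
#' peripheral cells and/or pushes the placement ring outward. Every day is
#' rendered from the same scene seed, so the series is deterministic, a
#' zero-growth series repeats day 0 identically, and each day's cell count
#' is exact bookkeeping: day `d` has `d * cells_added_per_day` more centers
#' than day 0.
#'
#' @param scene Base-day [spheroid_scene()].
#' @param days Number of days to render, at least 1 (day 0 alone).
#' @param growth List with any of `core_growth_per_day`,
#'   `cells_added_per_day`, `ring_expansion_per_day` (pixels, cells, pixels
#'   per day; all non-negative, default 0).
#' @param microns_per_pixel Optional calibration stamped on every image.
#' @return A list of `days` elements (day 0 first), each a [render_scene()]
#'   result plus a `day` field.
#' @export
render_series <- function(scene, days, growth = list(),
                          microns_per_pixel = NULL) {
  days <- as.integer(days)
  if (days < 1L) abort("`days` must be at least 1")
  g <- list(core_growth_per_day = 0, cells_added_per_day = 0L,
            ring_expansion_per_day = 0)
  g[names(growth)] <- growth
  if (any(unlist(g) < 0)) abort("growth parameters must be non-negative")
  lapply(seq_len(days) - 1L, function(d) {
    sc <- scene
    sc$core_radius <- scene$core_radius + d * g$core_growth_per_day
    sc$n_peripheral_cells <- scene$n_peripheral_cells +
      as.integer(d * g$cells_added_per_day)
    sc$placement_ring <- scene$placement_ring +
      c(0, d * g$ring_expansion_per_day)
    sc$placement_ring[1] <- sc$core_radius + sc$halo_width + 8
    if (sc$core_radius + sc$halo_width >= sc$image_size / 2 - 2) {
      abort(sprintf("day %d: grown core no longer fits inside the frame", d))
    }
    if (sc$n_peripheral_cells > 0L &&
        sc$placement_ring[1] >= sc$placement_ring[2]) {
      abort(sprintf("day %d: placement ring collapsed; increase ring_expansion_per_day", d))
    }
    sc$beyond_frame <- sc$placement_ring[2] > (sc$image_size - 1) / 2
    out <- render_scene(sc, microns_per_pixel = microns_per_pixel)
    out$day <- d
    out$image$label <- sprintf("synthetic-seed%d-day%d", sc$seed, d)
    out
  })
}

#' Render one scene under the four illumination-robustness conditions
#'
#' Convenience wrapper reproducing, at synthetic scale, the four acquisition
#' conditions used to probe illumination robustness: an artificially
#' introduced corner shadow, under-exposure, the average (flat) condition,
#' and high brightness with low contrast. The underlying scene, including
#' its noise field, is identical across the four renders.
#'
#' @param scene A [spheroid_scene()]; its own `illum` is ignored.
#' @param microns_per_pixel Optional calibration.
#' @return Named list (`shadow`, `underexposed`, `flat`,
#'   `bright_low_contrast`) of [render_scene()] results.
#' @export
render_illumination_set <- function(scene, microns_per_pixel = NULL) {
  kinds <- c(shadow = "corner_shadow", underexposed = "underexposed",
             flat = "flat", bright_low_contrast = "bright_low_contrast")
  lapply(kinds, function(k) {
    sc <- scene
    sc$illum <- illumination(k)
    render_scene(sc, microns_per_pixel = microns_per_pixel)
  })
}
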