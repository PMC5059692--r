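# Shared fixtures, built in code at test time.

# A compact spheroid with essentially no rim ramp: the regime where halo
# and core should nearly coincide.
sharp_scene <- function(seed = 1, ...) {
  spheroid_scene(core_radius = 90, halo_width = 0, seed = seed, ...)
}

# A smoothly spread-out spheroid: wide intensity ramp around a smaller
# core, the regime global thresholding under-covers.
diffuse_scene <- function(seed = 1, ...) {
  spheroid_scene(core_radius = 50, halo_width = 45, seed = seed, ...)
}

# Place Gaussian-profiled dark blobs on a flat background by hand;
# independent of the package's scene renderer.
blob_field <- function(n_blobs, rows, cols, size = 256, bg = 200,
                       contrast = 70, blob_sigma = 1.6) {
  px <- matrix(bg, size, size)
  for (i in seq_len(n_blobs)) {
    d2 <- outer((seq_len(size) - rows[i])^2, (seq_len(size) - cols[i])^2, `+`)
    px <- px - contrast * exp(-d2 / (2 * blob_sigma^2))
  }
  pmax(px, 0)
}

# Brute-force Otsu: for every candidate threshold compute the two class
# weights/means from the raw pixel values and the between-class variance
# straight from its definition.
otsu_brute <- function(px) {
  v <- pmin(floor(as.vector(px)), 255)
  best <- -Inf; arg <- integer()
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; arg <- t }
    else if (abs(sb - best) <= 1e-12) arg <- c(arg, t)
  }
  mean(arg)
}

# Brute-force seeded flood at one intensity ceiling: grow the seed by
# repeated 8-neighbour dilation into {intensity <= level} until stable.
flood_brute <- function(px, seed, level) {
  ok <- (px <= level) | seed
  cur <- seed
  repeat {
    grown <- cur
    idx <- which(cur, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      for (dr in -1:1) for (dc in -1:1) {
        r <- idx[k, 1] + dr; c <- idx[k, 2] + dc
        if (r >= 1 && r <= nrow(px) && c >= 1 && c <= ncol(px) && ok[r, c]) {
          grown[r, c] <- TRUE
        }
      }
    }
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

# Mean radial density falloff: average |d density / d radius| of the
# radial profile across an annulus.
radial_falloff <- function(map, r_in, r_out) {
  v <- map$values
  ctr <- (dim(v) + 1) / 2
  rr <- sqrt(outer((seq_len(nrow(v)) - ctr[1])^2,
                   (seq_len(ncol(v)) - ctr[2])^2, `+`))
  bins <- seq(r_in, r_out, by = 2)
  prof <- vapply(seq_len(length(bins) - 1), function(i) {
    sel <- rr >= bins[i] & rr < bins[i + 1]
    mean(v[sel])
  }, numeric(1))
  mean(abs(diff(prof))) / 2  # per pixel of radius
}
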