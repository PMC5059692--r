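test_that("level flooding matches a brute-force flood oracle on a toy grid", {
  set.seed(17)
  px <- matrix(sample(0:9, 64, replace = TRUE), 8, 8)
  seed <- matrix(FALSE, 8, 8); seed[4:5, 4:5] <- TRUE
  px[4:5, 4:5] <- 0
  levels <- 10L

  tr <- watershed_trace(px, seed, levels = levels)
  rng <- range(px)
  thresholds <- rng[1] + seq_len(levels) * diff(rng) / levels

  expect_identical(tr$iterations[[1]], seed)
  for (k in seq_len(tr$stop_index)) {
    expect_identical(unname(tr$iterations[[k + 1]]),
                     unname(flood_brute(px, seed, thresholds[k])),
                     label = sprintf("flood level %d", k))
  }

  # nested growth, and the stop step is the first to touch the border
  border <- rbind(matrix(TRUE, 1, 8), matrix(c(TRUE, rep(FALSE, 6), TRUE), 6, 8, byrow = TRUE), matrix(TRUE, 1, 8))
  for (k in seq_along(tr$iterations)[-1]) {
    expect_true(all(tr$iterations[[k - 1]] <= tr$iterations[[k]]))
  }
  n <- length(tr$iterations)
  expect_true(any(tr$iterations[[n]] & border))
  expect_false(any(tr$iterations[[n - 1]] & border))

  # the halo is the pre-border iteration of the same trace
  h <- extract_halo(px, seed, levels = levels)
  expect_equal(h$mask, tr$iterations[[tr$stop_index]], ignore_attr = TRUE)
  expect_equal(h$stop_index, tr$stop_index)
})

test_that("flooding traces are nested for random images and seeds", {
  set.seed(23)
  for (i in 1:4) {
    px <- matrix(sample(0:30, 144, replace = TRUE), 12, 12)
    seed <- matrix(FALSE, 12, 12)
    seed[6 + sample(-2:2, 1), 6 + sample(-2:2, 1)] <- TRUE
    tr <- watershed_trace(px, seed, levels = 16L)
    for (k in seq_along(tr$iterations)[-1]) {
      expect_true(all(tr$iterations[[k - 1]] <= tr$iterations[[k]]))
    }
    h <- extract_halo(px, seed, levels = 16L)
    expect_true(all(seed <= h$mask)) # halo contains the seed
    expect_false(any(h$mask & spherodens:::border_frame(c(12, 12))))
  }
})

test_that("halo nearly coincides with the core for a sharp compact spheroid", {
  r <- render_scene(sharp_scene(seed = 5))
  core <- extract_core(r$image)
  h <- extract_halo(r$image, core)
  expect_lt(abs(h$area_px / sum(core) - 1), 0.05)

  # on a noise-free sharp spheroid the halo stays within a 2-px band of
  # the core (with camera noise a handful of attached single-pixel
  # stragglers may sit just outside it)
  r0 <- render_scene(sharp_scene(seed = 5, noise_sigma = 0))
  core0 <- extract_core(r0$image)
  h0 <- extract_halo(r0$image, core0)
  ring <- EBImage::dilate(core0 * 1, EBImage::makeBrush(5, "disc")) != 0
  expect_true(all(h0$mask <= ring))
})

test_that("halo recovers the dense region of a spread-out spheroid", {
  r <- render_scene(diffuse_scene(seed = 8))
  core <- extract_core(r$image)
  h <- extract_halo(r$image, core)
  expect_gt(h$area_px, 1.2 * sum(core))
  expect_gt(sum(h$mask & r$truth$dense) / sum(r$truth$dense), 0.9)
})

test_that("halo area grows with the diffuse-ring width", {
  areas <- vapply(c(10, 25, 40), function(w) {
    r <- render_scene(spheroid_scene(core_radius = 50, halo_width = w, seed = 12))
    extract_halo(r$image, extract_core(r$image))$area_px
  }, numeric(1))
  expect_false(is.unsorted(areas, strictly = TRUE))
})

test_that("degenerate seeds are handled explicitly", {
  px <- matrix(100, 64, 64); px[20:40, 20:40] <- 40
  empty <- matrix(FALSE, 64, 64)
  expect_error(extract_halo(px, empty), "non-empty core")

  touching <- matrix(FALSE, 64, 64); touching[1:10, 1:10] <- TRUE
  expect_warning(h <- extract_halo(px, touching), "border")
  expect_true(h$degenerate)
  expect_equal(h$mask, touching, ignore_attr = TRUE)
})

test_that("halo area converts to square microns via the calibration", {
  r <- render_scene(sharp_scene(seed = 5), microns_per_pixel = 5.5)
  h <- extract_halo(r$image, extract_core(r$image))
  expect_equal(h$area_um2, h$area_px * 5.5^2)
  h2 <- extract_halo(r$image$pixels, extract_core(r$image))
  expect_true(is.na(h2$area_um2))
})
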