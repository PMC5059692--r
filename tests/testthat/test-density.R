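test_that("overlay is the pixel-wise union of the three regions", {
  core <- matrix(FALSE, 64, 64); core[20:40, 20:40] <- TRUE
  periph <- matrix(FALSE, 64, 64); periph[5:10, 50:60] <- TRUE

  ov <- combine_overlay(core, core, matrix(FALSE, 64, 64))
  expect_equal(ov, core, ignore_attr = TRUE)

  ov2 <- combine_overlay(core, core, periph)
  expect_equal(sum(ov2), sum(core) + sum(periph)) # disjoint union
  expect_true(all(core <= ov2) && all(periph <= ov2))

  expect_error(combine_overlay(core, core, matrix(FALSE, 32, 32)),
               "identical dimensions")
})

test_that("tile endpoints honor the 0-255 stretch rule", {
  full <- matrix(TRUE, 64, 64)
  m <- density_map(full, tile_size = 16, smoothing_sigma = 0)
  expect_true(all(m$values == 255))
  # a constant field is invariant under the smoothing pass
  ms <- density_map(full, tile_size = 16)
  expect_equal(max(abs(ms$values - 255)), 0, tolerance = 1e-9)

  expect_true(all(density_map(matrix(FALSE, 64, 64))$values == 0))
})

test_that("tile averages equal direct pixel counts", {
  ov <- matrix(FALSE, 32, 32)
  ov[1:8, 1:16] <- TRUE # half of the first 16x16 tile
  m <- density_map(ov, tile_size = 16, smoothing_sigma = 0)
  expect_equal(unique(as.vector(m$values[1:16, 1:16])), 127.5)
  expect_true(all(m$values[17:32, ] == 0))
  expect_true(all(m$values[1:16, 17:32] == 0))

  # partial edge tiles are averaged over their actual pixel count
  ov2 <- matrix(TRUE, 70, 70)
  m2 <- density_map(ov2, tile_size = 16, smoothing_sigma = 0)
  expect_true(all(m2$values == 255))

  # random overlays: each tile value is 255 * count / size, by direct count
  set.seed(7)
  ov3 <- matrix(runif(64 * 64) < 0.3, 64, 64)
  m3 <- density_map(ov3, tile_size = 16, smoothing_sigma = 0)
  for (ti in 1:4) for (tj in 1:4) {
    rows <- (ti - 1) * 16 + 1:16; cols <- (tj - 1) * 16 + 1:16
    expect_equal(unique(as.vector(m3$values[rows, cols])),
                 255 * sum(ov3[rows, cols]) / 256)
  }
})

test_that("tile averaging conserves integrated mass", {
  set.seed(19)
  ov <- matrix(runif(64 * 64) < 0.4, 64, 64)
  m <- density_map(ov, tile_size = 16, smoothing_sigma = 0)
  expect_equal(integrate_density(m), 255 * sum(ov), tolerance = 1e-9)

  expect_equal(integrate_density(density_map(matrix(FALSE, 64, 64))), 0)
  full <- density_map(matrix(TRUE, 64, 64), smoothing_sigma = 0)
  expect_equal(integrate_density(full), 255 * 64 * 64)
})

test_that("tile size larger than the image is rejected", {
  expect_error(density_map(matrix(TRUE, 32, 32), tile_size = 64), "tile_size")
})

test_that("relative series normalize to day 0 exactly", {
  ms <- tibble::tibble(label = "s1", day = c(0, 2, 4),
                       integrated_density = c(1000, 1500, 2000))
  rs <- relative_series(ms)
  expect_equal(rs$relative_size, c(1, 1.5, 2))

  shuffled <- ms[c(3, 1, 2), ]
  expect_equal(relative_series(shuffled)$relative_size, c(1, 1.5, 2))

  expect_error(relative_series(ms[-1, ]), "day-0")
  ms0 <- ms; ms0$integrated_density[1] <- 0
  expect_error(relative_series(ms0), "zero day-0")

  two <- dplyr::bind_rows(ms, dplyr::mutate(ms, label = "s2",
                                            integrated_density = c(500, 600, 900)))
  rs2 <- relative_series(two)
  expect_equal(rs2$relative_size[rs2$label == "s2"], c(1, 1.2, 1.8))
})

test_that("a growing synthetic series yields increasing relative sizes", {
  series <- render_series(spheroid_scene(core_radius = 40, halo_width = 4,
                                         n_peripheral_cells = 10, seed = 2),
                          days = 4,
                          growth = list(core_growth_per_day = 6,
                                        cells_added_per_day = 15,
                                        ring_expansion_per_day = 2))
  ms <- purrr::map2_dfr(series, seq_along(series) - 1, function(s, d) {
    measure_spheroid(s$image, day = d, label = "s")
  })
  rs <- relative_series(ms)
  expect_equal(rs$relative_size[1], 1)
  expect_false(is.unsorted(rs$relative_size, strictly = TRUE))
})

test_that("static debris common to all days largely cancels in the ratio", {
  series <- render_series(spheroid_scene(core_radius = 40, halo_width = 4,
                                         seed = 9),
                          days = 2,
                          growth = list(core_growth_per_day = 10))
  stamp_debris <- function(px) {
    set.seed(77)
    for (i in 1:12) {
      r0 <- sample(15:240, 1); c0 <- sample(15:240, 1)
      d2 <- outer((seq_len(256) - r0)^2, (seq_len(256) - c0)^2, `+`)
      px <- px - 80 * exp(-d2 / (2 * 2^2))
    }
    pmax(round(px), 0)
  }
  clean <- vapply(series, function(s)
    measure_spheroid(s$image)$integrated_density, numeric(1))
  dirty <- vapply(series, function(s)
    measure_spheroid(stamp_debris(s$image$pixels))$integrated_density,
    numeric(1))
  r_clean <- clean[2] / clean[1]
  r_dirty <- dirty[2] / dirty[1]
  expect_gt(r_dirty, 1)
  # the debris offset pulls the ratio toward 1 but not below it
  expect_lt(abs(r_dirty - r_clean) / (r_clean - 1), 0.5)
})

test_that("tidiers summarize a full single-image analysis", {
  r <- render_scene(spheroid_scene(n_peripheral_cells = 15, seed = 4),
                    microns_per_pixel = 5.5)
  an <- analyze_micrograph(r$image, label = "s1", day = 0L)
  td <- tidy(an)
  expect_setequal(td$region, c("core", "halo", "periphery", "overlay"))
  expect_true(all(td$area_px[td$region == "overlay"] >= td$area_px))
  gl <- glance(an)
  expect_equal(gl$label, "s1")
  expect_equal(gl$halo_area_um2, an$halo$area_px * 5.5^2)
  expect_equal(gl$integrated_density, integrate_density(an$density))
})
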