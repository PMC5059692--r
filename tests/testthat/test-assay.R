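# Build a small two-sample assay on disk: TIFF images plus a CSV manifest.
write_assay_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in 1:2) {
    series <- render_series(
      spheroid_scene(image_size = 128, core_radius = 24, halo_width = 3,
                     n_peripheral_cells = 8, placement_ring = c(36, 55),
                     seed = 40 + s),
      days = 3,
      growth = list(core_growth_per_day = 4, cells_added_per_day = 6))
    for (d in seq_along(series)) {
      f <- sprintf("s%d_day%d.tif", s, d - 1)
      save_micrograph(series[[d]]$image, file.path(dir, f))
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = paste0("s", s), day = d - 1L, path = f)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  file.path(dir, "manifest.csv")
}

test_that("run_assay produces a complete, day-0-normalized output tree", {
  dir <- withr::local_tempdir()
  man <- write_assay_fixture(file.path(dir, "in"))
  out <- file.path(dir, "out")
  res <- run_assay(man, out, microns_per_pixel = 5.5, quiet = TRUE)

  expect_equal(nrow(res$measurements), 6)
  expect_true(all(res$series$relative_size[res$series$day == 0] == 1))
  expect_true(all(res$series$relative_size >= 1))

  for (f in c("measurements.csv", "relative_sizes.csv", "run_manifest.json")) {
    expect_true(file.exists(file.path(out, f)))
  }
  expect_true(file.exists(file.path(out, "images", "s1_day0_overlay.png")))
  expect_true(file.exists(file.path(out, "images", "s2_day2_density.png")))
  expect_true(file.exists(file.path(out, "images", "s2_day2_density.csv")))

  audit <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_length(audit$inputs, 6)
  expect_equal(audit$config_hash, res$measurements$config_hash[1])
})

test_that("reruns are byte-identical and batch order does not matter", {
  dir <- withr::local_tempdir()
  man <- write_assay_fixture(file.path(dir, "in"))
  df <- read_manifest(man)

  out1 <- file.path(dir, "o1"); out2 <- file.path(dir, "o2")
  run_assay(df, out1, quiet = TRUE)
  run_assay(df[sample(nrow(df)), ], out2, quiet = TRUE)
  for (f in c("measurements.csv", "relative_sizes.csv")) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
})

test_that("manifest validation names missing day-0 samples and files", {
  dir <- withr::local_tempdir()
  man <- write_assay_fixture(file.path(dir, "in"))
  df <- read_manifest(man)

  expect_error(run_assay(df[df$day != 0 | df$label != "s2", ],
                         file.path(dir, "x"), quiet = TRUE), "s2")

  df2 <- df; df2$path[1] <- file.path(dir, "in", "ghost.tif")
  expect_error(run_assay(df2, file.path(dir, "x"), quiet = TRUE), "ghost")
})

test_that("YAML manifests resolve to the same table as CSV", {
  dir <- withr::local_tempdir()
  man <- write_assay_fixture(file.path(dir, "in"))
  df <- read_manifest(man)

  ym <- file.path(dir, "in", "manifest.yaml")
  samples <- split(df, df$label)
  yaml::write_yaml(list(samples = lapply(samples, function(g)
    as.list(setNames(basename(g$path), g$day)))), ym)
  df_y <- read_manifest(ym)
  expect_equal(dplyr::arrange(df_y, label, day),
               dplyr::arrange(df, label, day))
})

test_that("configs round-trip through YAML with documented keys", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(
    preprocess = list(gamma = 1.5, periphery_background_subtraction = TRUE),
    core = list(min_solidity = 0.5),
    halo = list(levels = 128),
    periphery = list(low = 10, high = 25),
    density = list(tile_size = 8)
  ), f)
  cfg <- read_config(f)
  expect_equal(cfg$preprocess$gamma, 1.5)
  expect_true(cfg$preprocess$periphery_background_subtraction)
  expect_equal(cfg$criteria$min_solidity, 0.5)
  expect_equal(cfg$halo_levels, 128L)
  expect_equal(cfg$canny$high_threshold, 25)
  expect_equal(cfg$tile_size, 8L)
  expect_equal(cfg$smoothing_sigma, 8L)
  expect_false(identical(spherodens:::config_hash(cfg),
                         spherodens:::config_hash(spherodens_config())))
})
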