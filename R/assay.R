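#' Read an input manifest
#'
#' A manifest maps every sample label to its ordered day-to-file series.
#' Explicit manifests are used instead of directory-name conventions because
#' accidentally pairing the wrong micrographs is a named failure mode of
#' invasion-assay analysis. Two formats are accepted:
#'
#' * CSV with columns `label`, `day`, `path`;
#' * YAML: `samples: {<label>: {<day>: <path>, ...}, ...}`.
#'
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest file (`.csv`, `.yml` or `.yaml`).
#' @return A tibble with columns `label`, `day` (integer), `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "csv") {
    tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  } else if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    if (is.null(y$samples)) abort("YAML manifest needs a top-level `samples` map")
    purrr::imap_dfr(y$samples, function(series, lab) {
      tibble::tibble(label = lab, day = as.integer(names(series)),
                     path = unlist(series, use.names = FALSE))
    })
  } else {
    abort("manifest must be a .csv or .yaml/.yml file")
  }
  if (!all(c("label", "day", "path") %in% names(df))) {
    abort("manifest needs columns `label`, `day`, `path`")
  }
  df$day <- as.integer(df$day)
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  validate_manifest(df)
  df[c("label", "day", "path")]
}

validate_manifest <- function(df) {
  missing0 <- setdiff(unique(df$label), df$label[df$day == 0L])
  if (length(missing0)) {
    abort(sprintf("sample(s) missing a day-0 entry: %s",
                  paste(missing0, collapse = ", ")))
  }
  dup <- df |> dplyr::count(.data$label, .data$day) |> dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicate (label, day) entries: %s",
                  paste(dup$label, dup$day, sep = "/", collapse = ", ")))
  }
  gone <- unique(df$path[!file.exists(df$path)])
  if (length(gone)) {
    abort(sprintf("manifest references missing file(s): %s",
                  paste(gone, collapse = ", ")))
  }
  invisible(df)
}

#' Batch-process an invasion assay
#'
#' Runs the full pipeline over every image of a manifest and writes a
#' reproducible output tree under `out_dir`:
#'
#' * `images/<label>_day<d>_overlay.png` — combined segmentation mask;
#' * `images/<label>_day<d>_density.png` — 8-bit density map;
#' * `images/<label>_day<d>_density.csv` — density map as a numeric grid;
#' * `measurements.csv` — one row per processed image;
#' * `relative_sizes.csv` — per-sample day-0-normalized series;
#' * `run_manifest.json` — full configuration plus an input content hash per
#'   image, so a results directory can be audited against its inputs.
#'
#' Processing is deterministic: rerunning on identical inputs and config
#' reproduces the CSVs byte for byte, and per-sample results do not depend
#' on batch order. A failing image is logged and skipped (its sample is
#' marked incomplete in the run manifest); only I/O or validation failures
#' before processing abort the run.
#'
#' @param manifest Path to a manifest file, or a data frame with columns
#'   `label`, `day`, `path` (every sample must include day 0).
#' @param out_dir Output directory (created if needed).
#' @param config A [spherodens_config()].
#' @param microns_per_pixel Optional calibration applied to every image.
#' @param quiet Suppress per-image progress messages.
#' @return Invisibly, a list with `measurements`, `series` (tibbles) and
#'   `incomplete` (labels with failed images).
#' @export
run_assay <- function(manifest, out_dir, config = spherodens_config(),
                      microns_per_pixel = NULL, quiet = FALSE) {
  df <- if (is.character(manifest)) read_manifest(manifest)
        else validate_manifest(tibble::as_tibble(manifest))
  df <- dplyr::arrange(df, .data$label, .data$day)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)

  failed <- character()
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    lab <- df$label[i]; day <- df$day[i]
    stem <- file.path(out_dir, "images", sprintf("%s_day%d", lab, day))
    res <- tryCatch({
      img <- load_micrograph(df$path[i], microns_per_pixel = microns_per_pixel,
                             label = lab)
      an <- analyze_micrograph(img, config, label = lab, day = day)
      save_mask(an$overlay, paste0(stem, "_overlay.png"))
      EBImage::writeImage(EBImage::Image(t(an$density$values) / 255),
                          paste0(stem, "_density.png"))
      write.csv(an$density$values, paste0(stem, "_density.csv"),
                row.names = FALSE)
      an$measurement
    }, error = function(e) {
      message(sprintf("image %s (day %d) failed: %s", lab, day,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failed <- c(failed, lab) else rows[[i]] <- res
    if (!quiet && !is.null(res)) {
      message(sprintf("processed %s day %d: integrated density %.1f",
                      lab, day, res$integrated_density))
    }
  }
  measurements <- dplyr::bind_rows(rows)
  if (!nrow(measurements)) abort("no image could be processed")

  complete <- measurements |>
    dplyr::filter(!.data$label %in% failed, .data$day == 0L) |>
    dplyr::pull(.data$label)
  series <- relative_series(dplyr::filter(measurements,
                                          .data$label %in% complete))
  write.csv(measurements, file.path(out_dir, "measurements.csv"),
            row.names = FALSE)
  write.csv(series, file.path(out_dir, "relative_sizes.csv"),
            row.names = FALSE)

  hashes <- setNames(
    vapply(df$path, function(p)
      rlang::hash(readBin(p, "raw", file.size(p))), character(1)),
    sprintf("%s_day%d", df$label, df$day))
  jsonlite::write_json(
    list(config = unclass_deep(config),
         config_hash = config_hash(config),
         inputs = as.list(hashes),
         incomplete_samples = unique(failed)),
    file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(measurements = measurements, series = series,
                 incomplete = unique(failed)))
}
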