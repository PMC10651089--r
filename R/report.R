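#' Run the full automated PSF analysis on a stack
#'
#' End-to-end, parameter-free pipeline: read the stack (if given a path),
#' build the multi-scale DOG representation, threshold it by Li's method, find
#' 3D local maxima, drop laterally crowded and border peaks, fit a 2D
#' elliptical Gaussian and a 1D axial Gaussian at each surviving peak, project
#' the fitted ellipses onto the image axes, and summarise the field of view.
#' Deterministic for a given input.
#'
#' @param x A TIFF file path or a [psf_stack()].
#' @param dx,dy,dz Optional calibration overrides in nm (beat file metadata).
#' @param channel Optional 0-based channel override (paths only).
#' @param radius Lateral fitting-patch radius in pixels.
#' @param min_separation Lateral exclusion distance between peaks, pixels.
#' @param max_peaks Cap on the number of analysed features.
#' @return A `psf_report`: list with `source`, `timestamp` (ISO-8601 UTC),
#'   `calibration`, `units` (`"nm"` or `"px"`), `characteristic_scale_px`,
#'   `n_features`, `features` (per-feature tibble, row order matches the
#'   overlay numbering), `summary` (a `psf_field_summary`), and `mip` (the
#'   maximum-intensity projection matrix). When nothing is detected the report
#'   is returned empty with a warning, not an error.
#' @export
analyze <- function(x, dx = NULL, dy = NULL, dz = NULL, channel = NULL,
                    radius = 5L, min_separation = 5, max_peaks = 200L) {
  stack <- if (is_psf_stack(x)) x else read_stack(x, channel = channel)
  if (!is.null(dx)) {
    stack$calibration$dx <- as.numeric(dx)
    if (is.null(dy)) stack$calibration$dy <- as.numeric(dx)  # square pixels
  }
  if (!is.null(dy)) stack$calibration$dy <- as.numeric(dy)
  if (!is.null(dz)) stack$calibration$dz <- as.numeric(dz)

  ss <- build_scale_space(stack)
  peaks <- find_peaks(ss, max_peaks = max_peaks)
  peaks <- exclude_close_peaks(peaks, min_separation = min_separation)

  # Axial init from calibration when available: scale the lateral
  # characteristic size by the voxel aspect, else reuse it as-is.
  cal <- stack$calibration
  init_z <- if (!is.na(cal$dx) && !is.na(cal$dz)) {
    max(1, ss$characteristic_scale * 2 * cal$dx / cal$dz)
  } else ss$characteristic_scale

  measurements <- if (nrow(peaks)) {
    measure_features(stack, peaks, init_sigma = ss$characteristic_scale,
                     init_sigma_z = init_z, radius = radius)
  } else {
    measure_features(stack, empty_peaks(), init_sigma = ss$characteristic_scale)
  }
  if (!nrow(peaks)) warning("no features detected; returning an empty report")

  lateral_nm <- suppressWarnings(lateral_pixel_nm(stack))
  units <- if (!is.na(lateral_nm) && !is.na(cal$dz)) "nm" else "px"

  structure(
    list(
      source = stack$source_name,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      calibration = cal,
      units = units,
      characteristic_scale_px = ss$characteristic_scale,
      n_features = nrow(measurements),
      features = measurements,
      summary = summarize_field(measurements),
      mip = max_projection(stack)
    ),
    class = "psf_report"
  )
}

#' @export
print.psf_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else format(v)
  cal <- x$calibration
  cat("== PSF analysis report ==\n",
      "file:      ", x$source, "\n",
      "timestamp: ", x$timestamp, "\n",
      "voxel (nm): dx=", fmt(cal$dx), " dy=", fmt(cal$dy), " dz=", fmt(cal$dz),
      "   [reported units: ", x$units, "]\n",
      "features:  ", x$n_features, " (", x$summary$n_ok, " fitted ok)\n\n",
      sep = "")
  print(x$summary$averages)
  invisible(x)
}

#' @method tidy psf_report
#' @export
tidy.psf_report <- function(x, ...) x$features

#' @method glance psf_report
#' @export
glance.psf_report <- function(x, ...) {
  g <- glance(x$summary)
  dplyr::bind_cols(tibble::tibble(source = x$source, units = x$units), g)
}

#' Export a report to CSV files
#'
#' Writes `averages.csv` (one row per summarised parameter) and `features.csv`
#' (one row per detected feature, ordered as in the overlay numbering). Plain
#' comma-separated UTF-8 with a header row, `.` decimal separator and `NA` for
#' absent values; every value in the averages file is recomputable from the
#' per-feature file.
#'
#' @param report A `psf_report` from [analyze()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector with the two file paths, invisibly.
#' @export
export_csv <- function(report, out_dir) {
  stopifnot(inherits(report, "psf_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  avg_path <- file.path(out_dir, "averages.csv")
  feat_path <- file.path(out_dir, "features.csv")

  avg <- report$summary$averages
  avg$units <- ifelse(avg$parameter %in% c("r2_xy", "r2_z"), "", report$units)
  utils::write.csv(avg, avg_path, row.names = FALSE, na = "NA")

  feat <- report$features
  feat$theta_deg <- feat$theta * 180 / pi
  cols <- c("index", "x", "y", "z", "cx", "cy", "cz",
            "fwhm_max_px", "fwhm_min_px", "theta_deg",
            "fwhm_x_px", "fwhm_y_px", "fwhm_z_px",
            "fwhm_max_nm", "fwhm_min_nm", "fwhm_x_nm", "fwhm_y_nm", "fwhm_z_nm",
            "r2_xy", "r2_z", "status")
  utils::write.csv(feat[, cols], feat_path, row.names = FALSE, na = "NA")
  invisible(c(averages = avg_path, features = feat_path))
}

#' Plot a report: maximum-intensity projection with numbered features
#'
#' @param object A `psf_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot psf_report
#' @export
autoplot.psf_report <- function(object, ...) {
  mip <- object$mip
  df <- tidyr::expand_grid(y = seq_len(nrow(mip)) - 1L, x = seq_len(ncol(mip)) - 1L)
  df$intensity <- as.vector(t(mip))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = object$source,
                  subtitle = paste0(object$n_features, " features; units: ", object$units)) +
    ggplot2::theme_minimal()
  if (nrow(object$features)) {
    p <- p + ggplot2::geom_text(
      data = object$features,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$index),
      colour = "red", size = 3
    )
  }
  p
}

#' Plot heat maps of a fitted parameter across the field of view
#'
#' @param object A `psf_field_summary` (or pass a `psf_report$summary`).
#' @param parameter Feature-table column to map, e.g. `"fwhm_max_nm"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot psf_field_summary
#' @export
autoplot.psf_field_summary <- function(object, parameter = "fwhm_max_px", ...) {
  feat <- object$features[object$features$status == "ok", , drop = FALSE]
  ggplot2::ggplot(feat, ggplot2::aes(x = .data$cx, y = .data$cy,
                                     colour = .data[[parameter]])) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_viridis_c(name = parameter) +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = paste0(parameter, " across the field of view")) +
    ggplot2::theme_minimal()
}

#' Benchmark this pipeline against a synthetic sweep
#'
#' Analyses every dataset of a sweep written by [generate_sweep()] and scores
#' the recovered FWHM values against the known truth. Per-dataset estimates are
#' the means over that dataset's successfully fitted features.
#'
#' @param manifest Sweep manifest tibble (or path to `manifest.csv`).
#' @param data_dir Directory holding the sweep TIFFs; defaults to the
#'   manifest's directory when a path is given.
#' @return [score_sweep()] records for every dataset.
#' @export
self_benchmark <- function(manifest, data_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(data_dir)) data_dir <- dirname(manifest)
    manifest <- tibble::as_tibble(utils::read.csv(manifest))
  }
  stopifnot(!is.null(data_dir))
  results <- dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
    rep <- suppressWarnings(analyze(file.path(data_dir, manifest$filename[i])))
    ok <- rep$features[rep$features$status == "ok", , drop = FALSE]
    tibble::tibble(
      dataset = manifest$dataset[i],
      X_E = if (nrow(ok)) mean(ok$fwhm_x_nm) else NA_real_,
      Y_E = if (nrow(ok)) mean(ok$fwhm_y_nm) else NA_real_,
      Z_E = if (nrow(ok)) mean(ok$fwhm_z_nm) else NA_real_
    )
  }))
  score_sweep(manifest, results)
}
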