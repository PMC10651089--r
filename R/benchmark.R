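#' Lateral percentage RMS error of estimated FWHM
#'
#' Root mean square of the x-axis and y-axis FWHM errors, expressed as a
#' percentage of the true lateral width and capped at 100:
#' `100 * sqrt(((X_E - W)^2 + (Y_E - W)^2) / 2) / W`. The division by two
#' inside the root makes this a true mean over the two axes (an un-averaged
#' variant would differ by sqrt(2)).
#'
#' @param x_e,y_e Estimated FWHM along x and y, nm (> 0); vectorised.
#' @param w_xy True lateral FWHM, nm (> 0).
#' @return Percentage(s) in `[0, 100]`.
#' @export
lateral_rmse_pct <- function(x_e, y_e, w_xy) {
  if (any(!is.finite(c(x_e, y_e, w_xy))) || any(x_e <= 0) || any(y_e <= 0) || any(w_xy <= 0)) {
    stop("domain error: all inputs must be positive", call. = FALSE)
  }
  pmin(100, 100 * sqrt(((x_e - w_xy)^2 + (y_e - w_xy)^2) / 2) / w_xy)
}

#' Axial percentage RMS error of estimated FWHM
#'
#' Single-axis case: `100 * |Z_E - W_Z| / W_Z`, capped at 100.
#'
#' @param z_e Estimated axial FWHM, nm (> 0); vectorised.
#' @param w_z True axial FWHM, nm (> 0).
#' @return Percentage(s) in `[0, 100]`.
#' @export
axial_rmse_pct <- function(z_e, w_z) {
  if (any(!is.finite(c(z_e, w_z))) || any(z_e <= 0) || any(w_z <= 0)) {
    stop("domain error: all inputs must be positive", call. = FALSE)
  }
  pmin(100, 100 * abs(z_e - w_z) / w_z)
}

#' Classify an RMSE percentage into the five reporting bands
#'
#' @param pct Percentage value(s).
#' @return Ordered factor with levels `<10%`, `10-20%`, `20-30%`, `30-40%`,
#'   `>40%`.
#' @export
rmse_band <- function(pct) {
  cut(pct, breaks = c(-Inf, 10, 20, 30, 40, Inf),
      labels = c("<10%", "10-20%", "20-30%", "30-40%", ">40%"),
      ordered_result = TRUE)
}

#' Score analyzer results against a synthetic sweep
#'
#' Joins per-dataset estimated FWHM values onto the sweep manifest and computes
#' lateral and axial percentage RMSE with the capping and failure conventions:
#' values above 100% are capped at 100, and a dataset with no returned estimate
#' (missing row or `NA`) is marked `failed` with RMSE 100.
#'
#' @param manifest Sweep manifest tibble from [generate_sweep()] (needs
#'   `dataset`, `A`, `B`, `SBR`, `dx`, `fwhm_xy`, `fwhm_z`).
#' @param results Tibble keyed by `dataset` with estimated `X_E`, `Y_E`, `Z_E`
#'   in nm (per-dataset means when several spots were measured). Every
#'   `dataset` value must exist in the manifest.
#' @return Tibble of benchmark records: manifest columns plus `X_E`, `Y_E`,
#'   `Z_E`, `lateral_rmse_pct`, `axial_rmse_pct`, `capped`, `failed`,
#'   `band_lateral`, `band_axial`.
#' @export
score_sweep <- function(manifest, results) {
  stopifnot(is.data.frame(manifest), is.data.frame(results))
  required <- c("dataset", "fwhm_xy", "fwhm_z")
  if (!all(required %in% names(manifest))) {
    stop("manifest must contain: ", paste(required, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(results$dataset, manifest$dataset)
  if (length(unknown)) {
    stop("consistency error: results contain unknown dataset id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(
    manifest,
    results[, intersect(c("dataset", "X_E", "Y_E", "Z_E"), names(results))],
    by = "dataset"
  )
  score_one <- function(x_e, y_e, z_e, w_xy, w_z) {
    lat_ok <- !is.na(x_e) && !is.na(y_e) && x_e > 0 && y_e > 0
    ax_ok <- !is.na(z_e) && z_e > 0
    lat_raw <- if (lat_ok) 100 * sqrt(((x_e - w_xy)^2 + (y_e - w_xy)^2) / 2) / w_xy else NA_real_
    ax_raw <- if (ax_ok) 100 * abs(z_e - w_z) / w_z else NA_real_
    tibble::tibble(
      lateral_rmse_pct = if (lat_ok) min(100, lat_raw) else 100,
      axial_rmse_pct = if (ax_ok) min(100, ax_raw) else 100,
      capped = (lat_ok && lat_raw > 100) || (ax_ok && ax_raw > 100),
      failed = !lat_ok || !ax_ok
    )
  }
  scores <- dplyr::bind_rows(purrr::pmap(
    list(joined$X_E, joined$Y_E, joined$Z_E, joined$fwhm_xy, joined$fwhm_z),
    score_one
  ))
  out <- dplyr::bind_cols(joined, scores)
  out$band_lateral <- rmse_band(out$lateral_rmse_pct)
  out$band_axial <- rmse_band(out$axial_rmse_pct)
  out
}

#' Heat-map of benchmark bands over the sweep grid
#'
#' Renders the pixel-size by SBR grid of RMSE bands (lateral or axial) as a
#' tile plot, mirroring the five-band classification used in reporting.
#'
#' @param records Output of [score_sweep()].
#' @param which `"lateral"` or `"axial"`.
#' @return A ggplot object.
#' @export
plot_benchmark_grid <- function(records, which = c("lateral", "axial")) {
  which <- match.arg(which)
  band_col <- if (which == "lateral") "band_lateral" else "band_axial"
  val_col <- if (which == "lateral") "lateral_rmse_pct" else "axial_rmse_pct"
  pal <- c("<10%" = "#1a9850", "10-20%" = "#91cf60", "20-30%" = "#fee08b",
           "30-40%" = "#fc8d59", ">40%" = "#d73027")
  ggplot2::ggplot(records, ggplot2::aes(
    x = factor(.data$SBR), y = factor(.data$dx), fill = .data[[band_col]])) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f", .data[[val_col]])), size = 3) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE, name = "RMSE(%)") +
    ggplot2::labs(x = "SBR", y = "lateral pixel size (nm)",
                  title = paste0(which, " FWHM error across the sweep")) +
    ggplot2::theme_minimal()
}
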