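#' Gaussian sigma-to-FWHM conversion factor
#'
#' For a Gaussian profile the full width at half maximum is
#' `2 * sqrt(2 * log(2)) * sigma` (about 2.35).
#'
#' @return The scalar factor.
#' @export
fwhm_factor <- function() 2 * sqrt(2 * log(2))

#' Convert a Gaussian sigma to FWHM
#'
#' @param sigma Gaussian width(s), > 0, in pixels.
#' @param pixel_size Pixel size in nm, or `NULL`/`NA` when the calibration is
#'   absent, in which case the FWHM is returned in pixel units.
#' @return FWHM in nm (calibrated) or pixels (uncalibrated), with attribute
#'   `"unit"` set to `"nm"` or `"px"`.
#' @export
sigma_to_fwhm <- function(sigma, pixel_size = NULL) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("domain error: sigma must be > 0", call. = FALSE)
  }
  if (is.null(pixel_size) || is.na(pixel_size)) {
    return(structure(fwhm_factor() * sigma, unit = "px"))
  }
  if (pixel_size <= 0) stop("domain error: pixel_size must be > 0", call. = FALSE)
  structure(fwhm_factor() * sigma * pixel_size, unit = "nm")
}

#' Extract the lateral patch and axial profile around a peak
#'
#' Selects a circular region of `radius` pixels around the peak in its z-plane
#' (pixels whose centre lies further than `radius + 0.5` from the peak are
#' masked `NA`) and the intensity-versus-z profile through the peak position
#' over the full axial extent.
#'
#' @param stack A [psf_stack()].
#' @param z,y,x 0-based voxel coordinates of the peak.
#' @param radius Patch radius in pixels.
#' @return List with `lateral` (a `(2*radius+1)^2` matrix with the circular
#'   mask applied), `axial` (numeric vector over z), `z`, `y`, `x`, and
#'   `status` — `"ok"`, or `"edge_rejected"` when the patch would leave the
#'   lateral field or the peak sits within one plane of the z borders.
#' @export
extract_patches <- function(stack, z, y, x, radius = 5L) {
  stopifnot(is_psf_stack(stack))
  d <- dim(stack$data)
  rejected <- list(lateral = NULL, axial = NULL, z = z, y = y, x = x, status = "edge_rejected")
  if (y < radius || y > d[2] - 1L - radius || x < radius || x > d[3] - 1L - radius) {
    return(rejected)
  }
  if (z < 1L || z > d[1] - 2L) return(rejected)

  iy <- (y - radius):(y + radius) + 1L
  ix <- (x - radius):(x + radius) + 1L
  patch <- stack$data[z + 1L, iy, ix]
  offs <- -radius:radius
  dist <- sqrt(outer(offs^2, offs^2, `+`))
  patch[dist > radius + 0.5] <- NA_real_
  list(lateral = patch, axial = stack$data[, y + 1L, x + 1L],
       z = z, y = y, x = x, status = "ok")
}

# Median of the unmasked pixels on the outer rim of the circular patch; a
# robust background estimate for fit initialisation.
patch_border_median <- function(patch) {
  r <- (nrow(patch) - 1L) / 2
  offs <- -r:r
  dist <- sqrt(outer(offs^2, offs^2, `+`))
  rim <- patch[dist > r - 0.5 & !is.na(patch)]
  if (!length(rim)) rim <- patch[!is.na(patch)]
  stats::median(rim)
}

#' Fit a rotated 2D elliptical Gaussian to a lateral patch
#'
#' Least-squares fit of
#' `offset + A * exp(-(u^2 / (2 sa^2) + v^2 / (2 sb^2)))`, where `(u, v)` are
#' patch coordinates rotated by `theta`, via Levenberg-Marquardt. The result is
#' canonicalised so `sigma_major >= sigma_minor` with `theta` the orientation
#' of the major axis relative to the image x axis, wrapped to `(-pi/2, pi/2]`.
#'
#' Initial estimates: offset = patch-border median, amplitude = peak value
#' minus that median, centre = patch centre, sigmas = `init_sigma`. Sigmas are
#' bounded to `[0.5, radius]` pixels; a fit converging onto a bound, or failing
#' to converge, is reported with `status = "fit_failed"`.
#'
#' @param patch Masked lateral patch from [extract_patches()] (at least 8
#'   unmasked pixels).
#' @param init_sigma Initial sigma estimate in pixels (e.g. the characteristic
#'   scale of the stack).
#' @return A `psf_fit2d` object: list with `center_y`, `center_x` (sub-pixel
#'   offsets from the patch centre), `sigma_major`, `sigma_minor`, `theta`,
#'   `amplitude`, `offset`, `r_squared`, `status`.
#' @export
fit_gaussian_2d <- function(patch, init_sigma) {
  stopifnot(is.matrix(patch), nrow(patch) == ncol(patch))
  ok <- !is.na(patch)
  if (sum(ok) < 8L) stop("at least 8 unmasked pixels required", call. = FALSE)
  radius <- (nrow(patch) - 1L) / 2
  offs <- -radius:radius
  uu <- matrix(offs, nrow(patch), ncol(patch))          # y offsets (rows)
  vv <- matrix(offs, nrow(patch), ncol(patch), byrow = TRUE)  # x offsets (cols)
  yobs <- patch[ok]; ug <- uu[ok]; vg <- vv[ok]

  bg0 <- patch_border_median(patch)
  a0 <- max(yobs) - bg0
  # On heavily oversampled data the true sigma can exceed the patch radius
  # (the patch then samples only the top of the blob, which still determines
  # the width in a least-squares sense), so the upper bound follows the
  # characteristic-scale initial estimate instead of being clamped to the
  # patch.
  s_hi <- max(radius, 3 * init_sigma)
  s0 <- min(max(init_sigma, 0.6), s_hi - 0.1)
  par0 <- c(offset = bg0, amp = max(a0, 1e-6), y0 = 0, x0 = 0,
            sa = s0, sb = s0, theta = 0)
  lower <- c(-Inf, 0, -radius, -radius, 0.5, 0.5, -pi)
  upper <- c(Inf, Inf, radius, radius, s_hi, s_hi, pi)

  model <- function(p) {
    ct <- cos(p[7]); st <- sin(p[7])
    u <- (vg - p[4]) * ct + (ug - p[3]) * st   # along-theta coordinate (x-axis reference)
    v <- -(vg - p[4]) * st + (ug - p[3]) * ct
    p[1] + p[2] * exp(-(u^2 / (2 * p[5]^2) + v^2 / (2 * p[6]^2)))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = function(p) yobs - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )

  failed_fit <- function() {
    structure(list(center_y = NA_real_, center_x = NA_real_,
                   sigma_major = NA_real_, sigma_minor = NA_real_,
                   theta = NA_real_, amplitude = NA_real_, offset = NA_real_,
                   r_squared = NA_real_, n_pixels = sum(ok), status = "fit_failed"),
              class = "psf_fit2d")
  }
  if (is.null(fit) || !fit$info %in% 1:4) return(failed_fit())
  p <- fit$par
  bound_tol <- 1e-4
  if (p[5] <= 0.5 + bound_tol || p[6] <= 0.5 + bound_tol ||
      p[5] >= s_hi - bound_tol || p[6] >= s_hi - bound_tol ||
      p[2] <= bound_tol) {
    return(failed_fit())
  }

  sa <- p[5]; sb <- p[6]; th <- p[7]
  if (sb > sa) { tmp <- sa; sa <- sb; sb <- tmp; th <- th + pi / 2 }
  th <- ((th + pi / 2) %% pi) - pi / 2       # wrap to (-pi/2, pi/2]
  if (th == -pi / 2) th <- pi / 2

  resid <- yobs - model(fit$par)
  ss_res <- sum(resid^2)
  ss_tot <- sum((yobs - mean(yobs))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else -Inf

  structure(list(center_y = unname(p[3]), center_x = unname(p[4]),
                 sigma_major = unname(sa), sigma_minor = unname(sb),
                 theta = unname(th), amplitude = unname(p[2]),
                 offset = unname(p[1]), r_squared = r2,
                 n_pixels = sum(ok), status = "ok"),
            class = "psf_fit2d")
}

#' Fit a 1D Gaussian to an axial intensity profile
#'
#' Least-squares fit of `offset + A * exp(-(z - z0)^2 / (2 sz^2))` to the
#' intensity-versus-plane profile through a feature, via Levenberg-Marquardt.
#'
#' @param profile Numeric vector of intensities over z (at least 5 samples,
#'   not constant).
#' @param init_sigma Initial sigma estimate in planes.
#' @return A `psf_fit1d` object: list with `center_z` (0-based sub-pixel
#'   plane), `sigma_z`, `amplitude`, `offset`, `r_squared`, `status`.
#' @export
fit_gaussian_1d <- function(profile, init_sigma) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 5L) stop("at least 5 axial samples required", call. = FALSE)

  failed_fit <- function() {
    structure(list(center_z = NA_real_, sigma_z = NA_real_,
                   amplitude = NA_real_, offset = NA_real_,
                   r_squared = NA_real_, status = "fit_failed"),
              class = "psf_fit1d")
  }
  if (max(profile) == min(profile)) return(failed_fit())

  zz <- seq_len(n) - 1
  bg0 <- stats::median(c(utils::head(profile, 2), utils::tail(profile, 2)))
  par0 <- c(offset = bg0, amp = max(max(profile) - bg0, 1e-6),
            z0 = which.max(profile) - 1, sz = min(max(init_sigma, 0.6), n / 2 - 0.1))
  lower <- c(-Inf, 0, 0, 0.5)
  upper <- c(Inf, Inf, n - 1, n / 2)

  model <- function(p) p[1] + p[2] * exp(-(zz - p[3])^2 / (2 * p[4]^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = function(p) profile - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) return(failed_fit())
  p <- fit$par
  bound_tol <- 1e-4
  if (p[4] <= 0.5 + bound_tol || p[4] >= n / 2 - bound_tol || p[2] <= bound_tol) {
    return(failed_fit())
  }
  resid <- profile - model(p)
  ss_tot <- sum((profile - mean(profile))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else -Inf

  structure(list(center_z = unname(p[3]), sigma_z = unname(p[4]),
                 amplitude = unname(p[2]), offset = unname(p[1]),
                 r_squared = r2, status = "ok"),
            class = "psf_fit1d")
}

#' @export
print.psf_fit2d <- function(x, ...) {
  if (x$status != "ok") { cat("<psf_fit2d> status:", x$status, "\n"); return(invisible(x)) }
  cat(sprintf("<psf_fit2d> sigma %.3f x %.3f px, theta %.1f deg, A %.1f, offset %.1f, R2 %.4f\n",
              x$sigma_major, x$sigma_minor, x$theta * 180 / pi, x$amplitude, x$offset, x$r_squared))
  invisible(x)
}

#' @export
print.psf_fit1d <- function(x, ...) {
  if (x$status != "ok") { cat("<psf_fit1d> status:", x$status, "\n"); return(invisible(x)) }
  cat(sprintf("<psf_fit1d> sigma %.3f planes at z0 %.2f, A %.1f, offset %.1f, R2 %.4f\n",
              x$sigma_z, x$center_z, x$amplitude, x$offset, x$r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy psf_fit2d
#' @export
tidy.psf_fit2d <- function(x, ...) {
  tibble::tibble(
    term = c("center_y", "center_x", "sigma_major", "sigma_minor", "theta", "amplitude", "offset"),
    estimate = c(x$center_y, x$center_x, x$sigma_major, x$sigma_minor, x$theta, x$amplitude, x$offset)
  )
}

#' @method glance psf_fit2d
#' @export
glance.psf_fit2d <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_pixels = x$n_pixels, status = x$status)
}

#' @method tidy psf_fit1d
#' @export
tidy.psf_fit1d <- function(x, ...) {
  tibble::tibble(term = c("center_z", "sigma_z", "amplitude", "offset"),
                 estimate = c(x$center_z, x$sigma_z, x$amplitude, x$offset))
}

#' @method glance psf_fit1d
#' @export
glance.psf_fit1d <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, status = x$status)
}

#' Fit every accepted peak and assemble the per-feature table
#'
#' Runs [extract_patches()], [fit_gaussian_2d()] and [fit_gaussian_1d()] for
#' each peak, converts sigmas to FWHM (nm when the relevant calibration is
#' present, pixel units otherwise) and adds the X/Y image-axis projections of
#' the fitted ellipse via [fwhm_xy_from_ellipse()].
#'
#' @param stack A [psf_stack()].
#' @param peaks Peak tibble from [find_peaks()] / [exclude_close_peaks()].
#' @param init_sigma Initial lateral sigma in pixels (characteristic scale).
#' @param init_sigma_z Initial axial sigma in planes; defaults to `init_sigma`.
#' @param radius Lateral patch radius in pixels.
#' @return Tibble with one row per peak: positions (0-based voxels and
#'   sub-pixel), fit parameters, `fwhm_*_px` always, `fwhm_*_nm` when
#'   calibrated (`NA` otherwise), `r2_xy`, `r2_z` and `status`
#'   (`ok` / `fit_failed` / `edge_rejected`).
#' @export
measure_features <- function(stack, peaks, init_sigma, init_sigma_z = init_sigma,
                             radius = 5L) {
  stopifnot(is_psf_stack(stack), is.data.frame(peaks))
  px_xy <- lateral_pixel_nm(stack)
  px_z <- stack$calibration$dz
  f <- fwhm_factor()

  empty_row <- tibble::tibble(
    index = integer(), z = integer(), y = integer(), x = integer(),
    response = numeric(), cz = numeric(), cy = numeric(), cx = numeric(),
    sigma_major = numeric(), sigma_minor = numeric(), theta = numeric(),
    sigma_z = numeric(), amplitude = numeric(), offset = numeric(),
    fwhm_max_px = numeric(), fwhm_min_px = numeric(), fwhm_x_px = numeric(),
    fwhm_y_px = numeric(), fwhm_z_px = numeric(), fwhm_max_nm = numeric(),
    fwhm_min_nm = numeric(), fwhm_x_nm = numeric(), fwhm_y_nm = numeric(),
    fwhm_z_nm = numeric(), r2_xy = numeric(), r2_z = numeric(),
    status = character()
  )
  if (nrow(peaks) == 0L) return(empty_row)

  rows <- purrr::pmap(list(peaks$z, peaks$y, peaks$x, peaks$response, seq_len(nrow(peaks))),
    function(z, y, x, response, idx) {
      base <- tibble::tibble(
        index = idx, z = z, y = y, x = x, response = response,
        cz = NA_real_, cy = NA_real_, cx = NA_real_,
        sigma_major = NA_real_, sigma_minor = NA_real_, theta = NA_real_,
        sigma_z = NA_real_, amplitude = NA_real_, offset = NA_real_,
        fwhm_max_px = NA_real_, fwhm_min_px = NA_real_,
        fwhm_x_px = NA_real_, fwhm_y_px = NA_real_, fwhm_z_px = NA_real_,
        fwhm_max_nm = NA_real_, fwhm_min_nm = NA_real_,
        fwhm_x_nm = NA_real_, fwhm_y_nm = NA_real_, fwhm_z_nm = NA_real_,
        r2_xy = NA_real_, r2_z = NA_real_, status = "ok"
      )
      patches <- extract_patches(stack, z, y, x, radius = radius)
      if (patches$status == "edge_rejected") { base$status <- "edge_rejected"; return(base) }
      fit2 <- fit_gaussian_2d(patches$lateral, init_sigma)
      fit1 <- fit_gaussian_1d(patches$axial, init_sigma_z)
      if (fit2$status != "ok" || fit1$status != "ok") { base$status <- "fit_failed"; return(base) }

      base$cz <- fit1$center_z
      base$cy <- y + fit2$center_y
      base$cx <- x + fit2$center_x
      base$sigma_major <- fit2$sigma_major
      base$sigma_minor <- fit2$sigma_minor
      base$theta <- fit2$theta
      base$sigma_z <- fit1$sigma_z
      base$amplitude <- fit2$amplitude
      base$offset <- fit2$offset
      base$r2_xy <- fit2$r_squared
      base$r2_z <- fit1$r_squared

      base$fwhm_max_px <- f * fit2$sigma_major
      base$fwhm_min_px <- f * fit2$sigma_minor
      proj_px <- fwhm_xy_from_ellipse(base$fwhm_max_px, base$fwhm_min_px, fit2$theta)
      base$fwhm_x_px <- proj_px$fwhm_x
      base$fwhm_y_px <- proj_px$fwhm_y
      base$fwhm_z_px <- f * fit1$sigma_z
      if (!is.na(px_xy)) {
        base$fwhm_max_nm <- base$fwhm_max_px * px_xy
        base$fwhm_min_nm <- base$fwhm_min_px * px_xy
        base$fwhm_x_nm <- base$fwhm_x_px * px_xy
        base$fwhm_y_nm <- base$fwhm_y_px * px_xy
      }
      if (!is.na(px_z)) base$fwhm_z_nm <- base$fwhm_z_px * px_z
      base
    })
  dplyr::bind_rows(rows)
}

#' Summarise fitted features across the field of view
#'
#' Computes the arithmetic mean and sample standard deviation of each fitted
#' parameter over the features with `status == "ok"`, in nm and pixel units,
#' plus mean fit-quality R-squared values. Failed fits are counted, never
#' imputed.
#'
#' @param measurements Per-feature tibble from [measure_features()].
#' @return A `psf_field_summary`: list with `n_detected`, `n_ok`, `n_failed`,
#'   `averages` (tibble: parameter, mean_nm, sd_nm, mean_px, sd_px, n) and the
#'   `features` table (ordered by detection index).
#' @export
summarize_field <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  ok <- measurements[measurements$status == "ok", , drop = FALSE]
  params <- c(fwhm_max = "fwhm_max", fwhm_min = "fwhm_min",
              fwhm_x = "fwhm_x", fwhm_y = "fwhm_y", fwhm_z = "fwhm_z")
  stat <- function(v, fun) if (nrow(ok) == 0L || all(is.na(v))) NA_real_ else fun(v, na.rm = TRUE)
  sdev <- function(v) if (nrow(ok) < 2L) NA_real_ else stat(v, stats::sd)
  averages <- dplyr::bind_rows(lapply(names(params), function(p) {
    tibble::tibble(
      parameter = p,
      mean_nm = stat(ok[[paste0(p, "_nm")]], mean),
      sd_nm = sdev(ok[[paste0(p, "_nm")]]),
      mean_px = stat(ok[[paste0(p, "_px")]], mean),
      sd_px = sdev(ok[[paste0(p, "_px")]]),
      n = nrow(ok)
    )
  }))
  averages <- dplyr::bind_rows(
    averages,
    tibble::tibble(parameter = c("r2_xy", "r2_z"),
                   mean_nm = NA_real_, sd_nm = NA_real_,
                   mean_px = c(stat(ok$r2_xy, mean), stat(ok$r2_z, mean)),
                   sd_px = c(sdev(ok$r2_xy), sdev(ok$r2_z)),
                   n = nrow(ok))
  )
  structure(
    list(n_detected = nrow(measurements), n_ok = nrow(ok),
         n_failed = sum(measurements$status != "ok"),
         averages = averages, features = measurements),
    class = "psf_field_summary"
  )
}

#' @export
print.psf_field_summary <- function(x, ...) {
  cat("<psf_field_summary> ", x$n_ok, " ok / ", x$n_detected, " detected features\n", sep = "")
  print(x$averages)
  invisible(x)
}

#' @method tidy psf_field_summary
#' @export
tidy.psf_field_summary <- function(x, ...) x$features

#' @method glance psf_field_summary
#' @export
glance.psf_field_summary <- function(x, ...) {
  avg <- x$averages
  g <- function(p, col) avg[[col]][avg$parameter == p]
  tibble::tibble(
    n_detected = x$n_detected, n_ok = x$n_ok, n_failed = x$n_failed,
    fwhm_lateral_nm = mean(c(g("fwhm_max", "mean_nm"), g("fwhm_min", "mean_nm"))),
    fwhm_axial_nm = g("fwhm_z", "mean_nm"),
    r2_xy = g("r2_xy", "mean_px"), r2_z = g("r2_z", "mean_px")
  )
}
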