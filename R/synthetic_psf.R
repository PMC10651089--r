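#' Specify a synthetic 3D Gaussian PSF dataset
#'
#' Full parameterisation of one synthetic bead dataset: a 3D Gaussian spot
#' model with lateral FWHM 273 nm and axial FWHM 1036 nm by default (the
#' theoretical PSF of a 1.15 NA water-immersion lens at 515 nm emission),
#' peak amplitude `A` counts above a uniform background `B = 100` counts, and
#' Poisson noise applied when a `seed` is given. The default lateral pixel
#' sizes used in the benchmark sweep are 10, 40, 80 and 160 nm; the axial step
#' defaults to 100 nm (about ten samples across the axial FWHM).
#'
#' @param fwhm_xy,fwhm_z True lateral and axial FWHM in nm.
#' @param amplitude Peak amplitude `A` in counts (> 0).
#' @param background Background offset `B` in counts (>= 0).
#' @param dx,dy,dz Voxel sizes in nm.
#' @param dim Optional `(z, y, x)` stack dimensions; when `NULL`, odd
#'   dimensions are chosen to cover at least four lateral sigmas and 3.5 axial
#'   sigmas around a centred spot (minimum 33 voxels per axis).
#' @param n_spots Number of spots (1 = centred spot; more are laid out on a
#'   square lateral grid, for detection tests).
#' @param seed Integer RNG seed for the Poisson step, or `NULL` for a
#'   noise-free dataset.
#' @return A `psf_synth_spec` list.
#' @export
synthetic_spec <- function(fwhm_xy = 273, fwhm_z = 1036,
                           amplitude = 1000, background = 100,
                           dx = 40, dy = dx, dz = 100,
                           dim = NULL, n_spots = 1L, seed = NULL) {
  stopifnot(fwhm_xy > 0, fwhm_z > 0, amplitude > 0, background >= 0,
            dx > 0, dy > 0, dz > 0, n_spots >= 1L)
  if (is.null(dim)) {
    s_xy_px <- fwhm_xy / fwhm_factor() / min(dx, dy)
    s_z_px <- fwhm_z / fwhm_factor() / dz
    half_xy <- max(16L, ceiling(4 * s_xy_px))
    half_z <- max(16L, ceiling(3.5 * s_z_px))
    side <- if (n_spots > 1L) {
      k <- ceiling(sqrt(n_spots))
      # grid pitch of 4 lateral sigmas or 12 px, whichever is larger
      pitch <- max(12L, ceiling(4 * s_xy_px))
      (k + 1L) * pitch + 2L * half_xy
    } else 2L * half_xy + 1L
    dim <- c(2L * half_z + 1L, side, side)
  }
  stopifnot(length(dim) == 3L, all(dim >= 3L))
  structure(
    list(fwhm_xy = fwhm_xy, fwhm_z = fwhm_z, amplitude = amplitude,
         background = background, dx = dx, dy = dy, dz = dz,
         dim = as.integer(dim), n_spots = as.integer(n_spots),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "psf_synth_spec"
  )
}

#' @export
print.psf_synth_spec <- function(x, ...) {
  cat(sprintf(
    "<psf_synth_spec> FWHM %g/%g nm, A=%g B=%g (SBR %.2f), voxel %g x %g x %g nm, dim %s, %d spot(s), %s\n",
    x$fwhm_xy, x$fwhm_z, x$amplitude, x$background,
    if (x$background > 0) sbr(x$amplitude, x$background) else NA,
    x$dx, x$dy, x$dz, paste(x$dim, collapse = "x"), x$n_spots,
    if (is.null(x$seed)) "noise-free" else paste0("seed ", x$seed)))
  invisible(x)
}

# Spot centres in 0-based voxel coordinates, list of c(z, y, x).
spot_centers <- function(spec) {
  d <- spec$dim
  cz <- (d[1] - 1) / 2
  if (spec$n_spots == 1L) return(list(c(cz, (d[2] - 1) / 2, (d[3] - 1) / 2)))
  k <- ceiling(sqrt(spec$n_spots))
  pos_y <- seq(0, d[2] - 1, length.out = k + 2)[2:(k + 1)]
  pos_x <- seq(0, d[3] - 1, length.out = k + 2)[2:(k + 1)]
  grid <- expand.grid(y = round(pos_y), x = round(pos_x))
  lapply(seq_len(spec$n_spots), function(i) c(cz, grid$y[i], grid$x[i]))
}

#' Render the noise-free synthetic stack
#'
#' Evaluates `B + A * exp(-(dx2 + dy2) / (2 sigma_xy^2) - dz2 / (2 sigma_z^2))`
#' at every voxel centre, with `sigma = FWHM / (2 sqrt(2 log 2))`, and sets the
#' stack calibration from `spec`.
#'
#' @param spec A [synthetic_spec()].
#' @return A [psf_stack()] of the noise-free model.
#' @export
render_noise_free <- function(spec) {
  stopifnot(inherits(spec, "psf_synth_spec"))
  d <- spec$dim
  s_xy <- spec$fwhm_xy / fwhm_factor()
  s_z <- spec$fwhm_z / fwhm_factor()

  centers <- spot_centers(spec)
  margin_xy <- 3 * s_xy / min(spec$dx, spec$dy)
  margin_z <- 3 * s_z / spec$dz
  for (ct in centers) {
    if (ct[1] < margin_z - 1e-9 || ct[1] > d[1] - 1 - margin_z + 1e-9 ||
        ct[2] < margin_xy - 1e-9 || ct[2] > d[2] - 1 - margin_xy + 1e-9 ||
        ct[3] < margin_xy - 1e-9 || ct[3] > d[3] - 1 - margin_xy + 1e-9) {
      stop("placement error: spot at (", paste(ct, collapse = ", "),
           ") is closer than 3 sigma to the stack border", call. = FALSE)
    }
  }

  arr <- array(0, d)
  for (ct in centers) {
    gz <- exp(-(((0:(d[1] - 1)) - ct[1]) * spec$dz)^2 / (2 * s_z^2))
    gy <- exp(-(((0:(d[2] - 1)) - ct[2]) * spec$dy)^2 / (2 * s_xy^2))
    gx <- exp(-(((0:(d[3] - 1)) - ct[3]) * spec$dx)^2 / (2 * s_xy^2))
    blob <- outer(outer(gz, gy), gx)
    dim(blob) <- d
    arr <- arr + spec$amplitude * blob
  }
  arr <- arr + spec$background

  psf_stack(arr, dx = spec$dx, dy = spec$dy, dz = spec$dz,
            source_name = sprintf("synthetic A=%g B=%g dx=%g", spec$amplitude,
                                  spec$background, spec$dx))
}

#' Apply Poisson noise to a stack
#'
#' Each voxel is independently replaced by a draw from a Poisson distribution
#' whose mean (and variance) is the voxel's noise-free intensity. The draw is
#' deterministic given `seed`; the global RNG state is left untouched.
#'
#' @param stack A non-negative [psf_stack()].
#' @param seed Integer seed.
#' @return A new [psf_stack()] with integer-valued intensities.
#' @export
apply_poisson_noise <- function(stack, seed) {
  stopifnot(is_psf_stack(stack))
  if (min(stack$data) < 0) stop("domain error: negative intensities", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  noisy <- stack
  noisy$data <- array(as.numeric(stats::rpois(length(stack$data), lambda = stack$data)),
                      dim(stack$data))
  noisy
}

#' Signal-to-background ratio
#'
#' `SBR = (A + B) / B` for a spot of peak amplitude `A` counts above a
#' background of `B` counts.
#'
#' @param A Peak amplitude(s), counts (>= 0).
#' @param B Background offset(s), counts (> 0).
#' @return The ratio(s).
#' @export
sbr <- function(A, B) {
  if (any(!is.finite(A)) || any(!is.finite(B)) || any(A < 0)) {
    stop("domain error: require finite A >= 0", call. = FALSE)
  }
  if (any(B <= 0)) stop("domain error: SBR undefined for B <= 0", call. = FALSE)
  (A + B) / B
}

#' Generate the factorial benchmark sweep of synthetic datasets
#'
#' Renders and writes one noisy TIFF per combination of lateral pixel size and
#' peak amplitude — by default 4 pixel sizes (10, 40, 80, 160 nm) times 8
#' amplitudes (50 to 1000 counts over background 100, SBR 1.5 to 11), i.e. 32
#' datasets — with a fixed axial step, plus a `manifest.csv` recording the model
#' and per-dataset seed. Per-dataset seeds are derived deterministically from
#' `base_seed`, so the same base seed reproduces byte-identical files.
#'
#' @param output_dir Writable directory (created if missing).
#' @param base_seed Integer base RNG seed.
#' @param dx_values Lateral pixel sizes in nm.
#' @param amplitudes Peak amplitudes in counts.
#' @param background Background counts.
#' @param dz Axial step in nm.
#' @param fwhm_xy,fwhm_z True model FWHM values in nm.
#' @return The manifest tibble (columns: dataset, filename, A, B, SBR, dx, dz,
#'   fwhm_xy, fwhm_z, seed), invisibly written to `output_dir/manifest.csv`.
#' @export
generate_sweep <- function(output_dir, base_seed,
                           dx_values = c(10, 40, 80, 160),
                           amplitudes = c(50, 100, 150, 200, 300, 500, 750, 1000),
                           background = 100, dz = 100,
                           fwhm_xy = 273, fwhm_z = 1036) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- expand.grid(A = amplitudes, dx = dx_values)  # amplitude varies fastest
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    A <- grid$A[i]; dx <- grid$dx[i]
    seed_i <- as.integer(base_seed) + i
    spec <- synthetic_spec(fwhm_xy = fwhm_xy, fwhm_z = fwhm_z, amplitude = A,
                           background = background, dx = dx, dz = dz, seed = seed_i)
    noisy <- apply_poisson_noise(render_noise_free(spec), seed_i)
    fn <- sprintf("psf_dx%03d_A%04d.tif", dx, A)
    write_stack(noisy, file.path(output_dir, fn))
    tibble::tibble(dataset = sub("\\.tif$", "", fn), filename = fn,
                   A = A, B = background, SBR = sbr(A, background),
                   dx = dx, dz = dz, fwhm_xy = fwhm_xy, fwhm_z = fwhm_z,
                   seed = seed_i)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
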