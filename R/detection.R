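#' Default scale set for the multi-scale representation
#'
#' Gaussian kernel widths (sigma, in pixels) used to build the difference-of-
#' Gaussians scale space: a geometric sequence from 1 to 16 px with the
#' standard octave-subdivision ratio of sqrt(2). Sub-resolution beads imaged
#' between heavy oversampling and near-Nyquist sampling land well inside this
#' range.
#'
#' @return Increasing numeric vector of sigmas in pixels.
#' @export
psf_scales <- function() 2^seq(0, 4, by = 0.5)

# Gaussian blur of a 3D array via its frequency response, periodic boundaries.
# The transfer function is exactly 1 at zero frequency, so the total image
# intensity (the MSR "energy") is conserved to machine precision.
gaussian_blur_3d <- function(arr, sigma) {
  d <- dim(arr)
  freq_sq <- function(n) {
    f <- c(0:(floor(n / 2)), if (n > 1) -((ceiling(n / 2) - 1):1) else NULL) / n
    f[seq_len(n)]^2
  }
  h1 <- exp(-2 * pi^2 * sigma^2 * freq_sq(d[1]))
  h2 <- exp(-2 * pi^2 * sigma^2 * freq_sq(d[2]))
  h3 <- exp(-2 * pi^2 * sigma^2 * freq_sq(d[3]))
  H <- outer(outer(h1, h2), h3)
  dim(H) <- d
  Re(stats::fft(stats::fft(arr) * H, inverse = TRUE)) / prod(d)
}

#' Build the multi-scale difference-of-Gaussians representation
#'
#' Blurs the stack with isotropic (in voxel units) Gaussian kernels of
#' increasing width, forms differences between copies adjacent in kernel size
#' (a band-pass filter), and reduces the sequence to a single volume by a
#' maximum intensity projection along the kernel-size axis. The adjacent-scale
#' difference is itself proportional to the scale-normalised Laplacian response
#' for the fixed sqrt(2) scale ratio, so its maximum tracks blob size: the
#' characteristic feature size is reported as the geometric mean of the scale
#' pair holding the globally largest difference value.
#'
#' Scales whose kernel support (2 sigma) exceeds the smallest stack dimension
#' are dropped; at least two usable scales must remain.
#'
#' @param stack A [psf_stack()].
#' @param scales Increasing vector of kernel sigmas in pixels.
#' @return A `psf_scale_space` object: list with `scales` (the usable scales),
#'   `dog_max_projection` (3D array), `characteristic_scale` (pixels), and
#'   `blur_sums` (total intensity of each blurred copy, for energy checks).
#' @export
build_scale_space <- function(stack, scales = psf_scales()) {
  stopifnot(is_psf_stack(stack))
  if (is.unsorted(scales, strictly = TRUE)) stop("`scales` must be strictly increasing", call. = FALSE)
  d <- dim(stack$data)
  usable <- scales[2 * scales <= min(d)]
  if (length(usable) < 2L) {
    stop("dimension error: stack (", paste(d, collapse = " x "),
         ") is smaller than the smallest kernel supports; no usable scale pair", call. = FALSE)
  }

  blurred <- lapply(usable, function(s) gaussian_blur_3d(stack$data, s))
  blur_sums <- vapply(blurred, sum, numeric(1))

  dog_max <- NULL
  best <- -Inf
  best_pair <- 1L
  for (i in seq_len(length(usable) - 1L)) {
    dog <- blurred[[i]] - blurred[[i + 1L]]
    m <- max(dog)
    if (m > best) { best <- m; best_pair <- i }
    dog_max <- if (is.null(dog_max)) dog else pmax(dog_max, dog)
  }

  structure(
    list(
      scales = usable,
      dog_max_projection = dog_max,
      characteristic_scale = sqrt(usable[best_pair] * usable[best_pair + 1L]),
      blur_sums = blur_sums,
      input_sum = sum(stack$data),
      dim = d
    ),
    class = "psf_scale_space"
  )
}

#' @export
print.psf_scale_space <- function(x, ...) {
  cat("<psf_scale_space> ", length(x$scales), " scales in [",
      format(min(x$scales)), ", ", format(max(x$scales)), "] px; ",
      "characteristic scale ", format(x$characteristic_scale, digits = 4), " px\n", sep = "")
  invisible(x)
}

#' Li's minimum cross-entropy threshold
#'
#' Computes the threshold minimising the cross-entropy between the intensities
#' and their two-level segmentation, by the fixed-point iteration
#' `t <- (mu_below - mu_above) / (log(mu_below) - log(mu_above))`
#' on the class means below/above the current threshold, iterated until the
#' update falls below `tol` times the intensity range.
#'
#' @param values Numeric vector of non-negative intensities with at least two
#'   distinct values.
#' @param tol Relative convergence tolerance on the threshold update.
#' @return The threshold (scalar). Values strictly above it are foreground.
#' @export
li_threshold <- function(values, tol = 1e-6) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (min(values) < 0) stop("values must be non-negative", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) stop("degenerate input: all values identical", call. = FALSE)

  eps <- .Machine$double.eps
  t_cur <- mean(values)
  tol_abs <- max(tol * (rng[2] - rng[1]), eps)
  for (iter in seq_len(100L)) {
    below <- values[values <= t_cur]
    above <- values[values > t_cur]
    mu_b <- if (length(below)) mean(below) else eps
    mu_a <- if (length(above)) mean(above) else rng[2]
    mu_b <- max(mu_b, eps)
    mu_a <- max(mu_a, eps)
    t_new <- if (mu_b == mu_a) t_cur else (mu_b - mu_a) / (log(mu_b) - log(mu_a))
    if (abs(t_new - t_cur) < tol_abs) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Find candidate feature peaks in the scale space
#'
#' Returns voxels of the DOG maximum projection that are local maxima over
#' their full 26-neighbourhood and exceed Li's cross-entropy threshold of that
#' volume. On a plateau of equal values the first voxel in `(z, y, x)` scan
#' order is kept. Peaks are sorted by descending response and truncated to the
#' `max_peaks` strongest (the analysis handles up to 200 beads per field).
#'
#' @param ss A `psf_scale_space` from [build_scale_space()].
#' @param max_peaks Maximum number of peaks returned.
#' @return Tibble with 0-based voxel coordinates `z`, `y`, `x`, the DOG
#'   `response` and `above_threshold` (always `TRUE` for returned rows). Empty
#'   when nothing rises above threshold (e.g. featureless or constant input).
#' @export
find_peaks <- function(ss, max_peaks = 200L) {
  stopifnot(inherits(ss, "psf_scale_space"))
  vol <- ss$dog_max_projection
  d <- dim(vol)

  # A featureless stack produces a DOG volume that is numerically zero
  # relative to the image intensity scale; nothing to detect.
  mean_intensity <- ss$input_sum / prod(d)
  if (max(vol) <= 1e-9 * max(mean_intensity, .Machine$double.eps)) {
    return(empty_peaks())
  }
  thr <- tryCatch(
    li_threshold(as.vector(vol) - min(vol)) + min(vol),
    error = function(e) NA_real_  # constant volume: nothing to detect
  )
  if (is.na(thr)) return(empty_peaks())

  # Strict local maxima over the 26-neighbourhood, with deterministic
  # first-in-scan-order tie-breaking on plateaus: require ">" against
  # neighbours earlier in linear (column-major, z fastest) order and ">="
  # against later ones.
  core <- vol[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE]
  is_max <- array(TRUE, dim(core))
  for (ddz in -1:1) for (ddy in -1:1) for (ddx in -1:1) {
    if (ddz == 0 && ddy == 0 && ddx == 0) next
    nb <- vol[2:(d[1] - 1) + ddz, 2:(d[2] - 1) + ddy, 2:(d[3] - 1) + ddx, drop = FALSE]
    lin <- ddz + ddy * d[1] + ddx * d[1] * d[2]
    is_max <- is_max & (if (lin < 0) core > nb else core >= nb)
  }
  sel <- which(is_max & core > thr, arr.ind = TRUE)
  if (nrow(sel) == 0L) return(empty_peaks())

  resp <- core[is_max & core > thr]
  # back to full-volume 0-based coordinates
  out <- tibble::tibble(
    z = as.integer(sel[, 1]),     # core index 1 == full index 2 == 0-based 1
    y = as.integer(sel[, 2]),
    x = as.integer(sel[, 3]),
    response = as.numeric(resp),
    above_threshold = TRUE
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$response), .data$z, .data$y, .data$x)
  utils::head(out, max_peaks)
}

empty_peaks <- function() {
  tibble::tibble(z = integer(), y = integer(), x = integer(),
                 response = numeric(), above_threshold = logical())
}

#' Drop peaks that are laterally too close together
#'
#' Any peak participating in at least one pair with lateral (y, x) Euclidean
#' distance below `min_separation` is removed — both members of the pair, since
#' neither can be fitted cleanly inside its circular patch. Surviving peaks are
#' pairwise at least `min_separation` apart. The operation is idempotent and
#' independent of row order.
#'
#' @param peaks Tibble from [find_peaks()].
#' @param min_separation Minimum allowed lateral distance in pixels.
#' @return The filtered peaks tibble.
#' @export
exclude_close_peaks <- function(peaks, min_separation = 5) {
  stopifnot(is.data.frame(peaks))
  n <- nrow(peaks)
  if (n < 2L) return(peaks)
  dmat <- as.matrix(stats::dist(cbind(peaks$y, peaks$x)))
  diag(dmat) <- Inf
  keep <- apply(dmat, 1L, min) >= min_separation
  peaks[keep, , drop = FALSE]
}
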