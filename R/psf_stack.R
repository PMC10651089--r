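#' Create a calibrated 3D image stack
#'
#' `psf_stack()` is the internal container for a single-channel z-stack. The
#' intensity data are stored as a 3D array indexed `(z, y, x)` and promoted to
#' double. Voxel calibration is carried in nanometres; an absent calibration
#' value is `NA` and is propagated (never silently replaced by a default) so
#' that downstream widths fall back to pixel units.
#'
#' @param data 3D numeric array indexed `(z, y, x)`; all values finite and
#'   non-negative. At least 3 planes in z and 16 pixels in y and x.
#' @param dx,dy,dz Voxel dimensions in nm (`NA` when unknown). Must be > 0
#'   when present.
#' @param source_name Provenance label (usually the file name).
#' @param channel_index 0-based index of the colour channel the data came from.
#' @return An object of class `psf_stack`.
#' @examples
#' s <- psf_stack(array(1, c(4, 20, 20)), dx = 40, dy = 40, dz = 100)
#' dim(s$data)
#' @export
psf_stack <- function(data, dx = NA_real_, dy = NA_real_, dz = NA_real_,
                      source_name = "<in-memory>", channel_index = 0L) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array indexed (z, y, x)", call. = FALSE)
  }
  d <- dim(data)
  if (d[1] < 3L || d[2] < 16L || d[3] < 16L) {
    stop("dimension error: stack must have >= 3 z-planes and >= 16 pixels in y and x (got ",
         paste(d, collapse = " x "), ")", call. = FALSE)
  }
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    stop("stack intensities must all be finite", call. = FALSE)
  }
  if (min(data) < 0) {
    stop("stack intensities must be non-negative", call. = FALSE)
  }
  for (v in list(dx = dx, dy = dy, dz = dz)) {
    if (!is.na(v) && v <= 0) stop("voxel sizes must be > 0 when present", call. = FALSE)
  }
  structure(
    list(
      data = data,
      calibration = list(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz)),
      source_name = source_name,
      channel_index = as.integer(channel_index)
    ),
    class = "psf_stack"
  )
}

#' @export
print.psf_stack <- function(x, ...) {
  d <- dim(x$data)
  cal <- x$calibration
  fmt <- function(v) if (is.na(v)) "NA" else format(v)
  cat("<psf_stack> ", x$source_name, "\n",
      "  dims (z, y, x): ", paste(d, collapse = " x "), "\n",
      "  voxel (nm): dx=", fmt(cal$dx), " dy=", fmt(cal$dy), " dz=", fmt(cal$dz), "\n",
      "  channel: ", x$channel_index,
      "   intensity range: [", format(min(x$data)), ", ", format(max(x$data)), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.psf_stack <- function(x) dim(x$data)

is_psf_stack <- function(x) inherits(x, "psf_stack")

#' Lateral pixel size usable for nm conversion
#'
#' Returns `dx` when the lateral calibration is square (dx == dy), otherwise
#' `NA` with a warning: converting an elliptical fit to nm is only well defined
#' on square pixels.
#' @noRd
lateral_pixel_nm <- function(stack) {
  dx <- stack$calibration$dx
  dy <- stack$calibration$dy
  if (is.na(dx) || is.na(dy)) return(NA_real_)
  if (!isTRUE(all.equal(dx, dy, tolerance = 1e-9))) {
    warning("non-square lateral pixels (dx != dy): lateral widths reported in pixels only")
    return(NA_real_)
  }
  dx
}

#' Maximum intensity projection along z
#'
#' @param stack A [psf_stack()].
#' @return A `(y, x)` matrix of per-pixel maxima over z.
#' @export
max_projection <- function(stack) {
  stopifnot(is_psf_stack(stack))
  apply(stack$data, c(2, 3), max)
}
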