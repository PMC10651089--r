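#' Reduce an ellipse inclination to the first quadrant
#'
#' The x/y projections of an inclined ellipse are unchanged by reflecting the
#' inclination: `-theta` projects identically to `theta`, and angles past
#' `pi/2` map back down symmetrically until zero at `pi`. This reduces any
#' finite angle to the equivalent one in `[0, pi/2]`.
#'
#' @param theta Inclination(s) in radians.
#' @return Angle(s) in `[0, pi/2]` with identical projections.
#' @export
normalize_theta <- function(theta) {
  stopifnot(all(is.finite(theta)))
  th <- abs(theta) %% pi
  ifelse(th > pi / 2, pi - th, th)
}

#' Project a rotated ellipse onto the image axes
#'
#' Computes the full horizontal and vertical extents `X'` and `Y'` of an
#' ellipse with semi-axes `a >= b` inclined at `theta` to the x axis. The naive
#' `2 a cos(theta)` underestimates the true extent; instead the parametric
#' angles `eps_x`, `eps_y` of the extreme (vertical/horizontal-tangent) points
#' are found from the vertex-gradient conditions — the boundary gradient equals
#' `cot(theta)` at the x-extreme point and `-tan(theta)` at the y-extreme point
#' of the unrotated ellipse — giving `tan(eps_x) = -(b/a) tan(theta)` and
#' `tan(eps_y) = (b/a) cot(theta)`. The centre chords through the two extreme
#' points (`k_x`, `k_y`) then project onto the axes.
#'
#' The result equals the closed-form bounding box of a rotated ellipse,
#' `X' = 2 sqrt(a^2 cos^2 theta + b^2 sin^2 theta)` and
#' `Y' = 2 sqrt(a^2 sin^2 theta + b^2 cos^2 theta)`.
#'
#' @param a,b Semi-major and semi-minor half-widths (`a >= b > 0`).
#' @param theta Inclination of the major axis to the x axis, radians (any
#'   finite value; reduced via [normalize_theta()]).
#' @return One-row tibble: `x_extent`, `y_extent`, `eps_x`, `eps_y`, `k_x`,
#'   `k_y`.
#' @export
project_ellipse <- function(a, b, theta) {
  stopifnot(length(a) == 1L, length(b) == 1L, length(theta) == 1L)
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a < b) {
    stop("require a >= b > 0", call. = FALSE)
  }
  th <- normalize_theta(theta)

  # Degenerate inclinations (and the circle) have axis-aligned answers and
  # would put cot/tan at a pole; short-circuit them.
  if (a == b) {
    return(tibble::tibble(x_extent = 2 * a, y_extent = 2 * a,
                          eps_x = 0, eps_y = pi / 2, k_x = 2 * a, k_y = 2 * a))
  }
  if (th < 1e-12) {
    return(tibble::tibble(x_extent = 2 * a, y_extent = 2 * b,
                          eps_x = 0, eps_y = pi / 2, k_x = 2 * a, k_y = 2 * b))
  }
  if (abs(th - pi / 2) < 1e-12) {
    return(tibble::tibble(x_extent = 2 * b, y_extent = 2 * a,
                          eps_x = pi / 2, eps_y = 0, k_x = 2 * b, k_y = 2 * a))
  }

  # Parametric angles of the extreme boundary points.
  eps_x <- atan(-(b / a) * tan(th))
  eps_y <- atan((b / a) / tan(th))

  # Centre chords through the two opposite extreme points (ellipse chord
  # length at parametric angle eps).
  chord <- function(eps) 2 * sqrt((a * cos(eps))^2 + (b * sin(eps))^2)
  k_x <- chord(eps_x)
  k_y <- chord(eps_y)

  # Extreme point rotated by theta; twice its coordinate is the extent.
  x_extent <- 2 * abs(a * cos(eps_x) * cos(th) - b * sin(eps_x) * sin(th))
  y_extent <- 2 * abs(a * cos(eps_y) * sin(th) + b * sin(eps_y) * cos(th))

  tibble::tibble(x_extent = x_extent, y_extent = y_extent,
                 eps_x = eps_x, eps_y = eps_y, k_x = k_x, k_y = k_y)
}

#' Map elliptical FWHM values to image-axis FWHM values
#'
#' Converts a fitted spot described by its maximum/minimum FWHM and major-axis
#' orientation into the widths seen when projecting onto the image X and Y
#' axes, for comparison with tools that report axis-aligned widths. The ellipse
#' semi-axes are half the FWHM values. There is not enough information for the
#' reverse mapping.
#'
#' @param fwhm_max,fwhm_min Maximum and minimum FWHM (same unit,
#'   `fwhm_max >= fwhm_min > 0`); vectorised.
#' @param theta Major-axis orientation(s) in radians.
#' @return Tibble with columns `fwhm_x`, `fwhm_y` in the input unit.
#' @export
fwhm_xy_from_ellipse <- function(fwhm_max, fwhm_min, theta) {
  n <- max(length(fwhm_max), length(fwhm_min), length(theta))
  fwhm_max <- rep_len(fwhm_max, n); fwhm_min <- rep_len(fwhm_min, n)
  theta <- rep_len(theta, n)
  if (any(!is.finite(fwhm_max) | !is.finite(fwhm_min) |
          fwhm_min <= 0 | fwhm_max < fwhm_min)) {
    stop("require fwhm_max >= fwhm_min > 0", call. = FALSE)
  }
  res <- purrr::pmap(list(fwhm_max / 2, fwhm_min / 2, theta),
                     function(a, b, th) project_ellipse(a, b, th))
  res <- dplyr::bind_rows(res)
  tibble::tibble(fwhm_x = res$x_extent, fwhm_y = res$y_extent)
}
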