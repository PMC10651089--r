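# Shared in-code fixtures: analytic Gaussian blobs rendered directly into
# arrays, independent of the synthetic-data module (so detection/fitting tests
# do not lean on the code they exercise).

# One or more isotropic-in-xy Gaussian blobs in a (z, y, x) array.
# centers: list of c(z, y, x) in 0-based voxel coordinates.
blob_array <- function(dim, centers, s_xy, s_z, amplitude = 100, background = 0) {
  arr <- array(0, dim)
  for (ct in centers) {
    gz <- exp(-((0:(dim[1] - 1)) - ct[1])^2 / (2 * s_z^2))
    gy <- exp(-((0:(dim[2] - 1)) - ct[2])^2 / (2 * s_xy^2))
    gx <- exp(-((0:(dim[3] - 1)) - ct[3])^2 / (2 * s_xy^2))
    b <- outer(outer(gz, gy), gx)
    dim(b) <- dim
    arr <- arr + amplitude * b
  }
  arr + background
}

blob_stack <- function(dim, centers, s_xy, s_z, amplitude = 100, background = 0, ...) {
  psf_stack(blob_array(dim, centers, s_xy, s_z, amplitude, background), ...)
}

# Noise-free sampled 2D elliptical Gaussian patch with circular mask applied,
# mirroring the patch geometry used by extract_patches.
gauss_patch <- function(radius, sx, sy, theta = 0, amplitude = 100,
                        offset = 10, cy = 0, cx = 0) {
  offs <- -radius:radius
  uu <- matrix(offs, 2 * radius + 1, 2 * radius + 1)            # y
  vv <- matrix(offs, 2 * radius + 1, 2 * radius + 1, byrow = TRUE)  # x
  ct <- cos(theta); st <- sin(theta)
  u <- (vv - cx) * ct + (uu - cy) * st
  v <- -(vv - cx) * st + (uu - cy) * ct
  patch <- offset + amplitude * exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
  dist <- sqrt(outer(offs^2, offs^2, `+`))
  patch[dist > radius + 0.5] <- NA_real_
  patch
}

# Exhaustive minimiser of the Li cross-entropy objective over all candidate
# thresholds (midpoints between adjacent distinct values).
li_brute_force <- function(v) {
  u <- sort(unique(v))
  cand <- (u[-1] + u[-length(u)]) / 2
  obj <- vapply(cand, li_cross_entropy, numeric(1), v = v)
  cand[which.min(obj)]
}

li_cross_entropy <- function(t, v) {
  lo <- v[v <= t]; hi <- v[v > t]
  if (!length(lo) || !length(hi)) return(Inf)
  -(sum(lo) * log(mean(lo)) + sum(hi) * log(mean(hi)))
}
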