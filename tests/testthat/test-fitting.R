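test_that("sigma-to-FWHM conversion uses 2*sqrt(2*log(2))", {
  expect_equal(signif(fwhm_factor(), 3), 2.35)
  f <- sigma_to_fwhm(1, pixel_size = 1)
  expect_equal(signif(as.numeric(f), 3), 2.35)
  expect_identical(attr(f, "unit"), "nm")

  # half-maximum crossing of the analytic Gaussian: FWHM 273 nm <-> sigma 115.92 nm
  expect_equal(as.numeric(sigma_to_fwhm(115.92, 1)), 273, tolerance = 1e-3)

  p <- sigma_to_fwhm(2, pixel_size = NA)
  expect_identical(attr(p, "unit"), "px")
  expect_equal(as.numeric(p), 2 * fwhm_factor())

  expect_error(sigma_to_fwhm(0), "domain error")
  expect_error(sigma_to_fwhm(-1, 40), "domain error")
})

test_that("radius-5 patch has 97 unmasked pixels and the peak's axial profile", {
  st <- blob_stack(c(15, 33, 33), list(c(7, 16, 16)), s_xy = 2, s_z = 2,
                   amplitude = 100, background = 10)
  p <- extract_patches(st, z = 7, y = 16, x = 16, radius = 5)
  expect_identical(p$status, "ok")
  expect_identical(dim(p$lateral), c(11L, 11L))
  expect_identical(sum(!is.na(p$lateral)), 97L)
  expect_length(p$axial, 15L)
  expect_identical(which.max(p$axial) - 1L, 7L)
})

test_that("peaks too close to a border are edge-rejected", {
  st <- blob_stack(c(15, 33, 33), list(c(7, 16, 16)), s_xy = 2, s_z = 2)
  expect_identical(extract_patches(st, 7, 2, 16, radius = 5)$status, "edge_rejected")
  expect_identical(extract_patches(st, 7, 16, 30, radius = 5)$status, "edge_rejected")
  expect_identical(extract_patches(st, 0, 16, 16, radius = 5)$status, "edge_rejected")
  expect_identical(extract_patches(st, 14, 16, 16, radius = 5)$status, "edge_rejected")
})

test_that("2D fit recovers noise-free Gaussians, isotropic and rotated", {
  fit <- fit_gaussian_2d(gauss_patch(5, sx = 2, sy = 2), init_sigma = 2.4)
  expect_identical(fit$status, "ok")
  expect_equal(fit$sigma_major, 2, tolerance = 0.005)
  expect_equal(fit$sigma_minor, 2, tolerance = 0.005)
  expect_gt(fit$r_squared, 0.999)

  fit2 <- fit_gaussian_2d(gauss_patch(5, sx = 3, sy = 1.5, theta = pi / 6),
                          init_sigma = 2.4)
  expect_identical(fit2$status, "ok")
  expect_equal(fit2$sigma_major, 3, tolerance = 0.02)
  expect_equal(fit2$sigma_minor, 1.5, tolerance = 0.02)
  expect_equal(fit2$theta, pi / 6, tolerance = 0.02)

  # sub-pixel centre
  fit3 <- fit_gaussian_2d(gauss_patch(5, 2, 2, cy = 0.4, cx = -0.3), init_sigma = 2)
  expect_equal(fit3$center_y, 0.4, tolerance = 0.01)
  expect_equal(fit3$center_x, -0.3, tolerance = 0.01)
})

test_that("flat or invalid patches fail cleanly", {
  flat <- gauss_patch(5, 2, 2, amplitude = 0, offset = 50)
  fit <- fit_gaussian_2d(flat, init_sigma = 2)
  expect_true(fit$status == "fit_failed" || fit$r_squared <= 0)

  tiny <- matrix(NA_real_, 11, 11)
  tiny[6, 6] <- 1
  expect_error(fit_gaussian_2d(tiny, 2), "8 unmasked")
})

test_that("fits of a 90-degree-rotated patch swap axes consistently", {
  patch <- gauss_patch(5, sx = 3, sy = 1.5, theta = pi / 7)
  rot90 <- t(patch)[, rev(seq_len(ncol(patch)))]   # anticlockwise 90 deg
  f1 <- fit_gaussian_2d(patch, 2)
  f2 <- fit_gaussian_2d(rot90, 2)
  expect_equal(f1$sigma_major, f2$sigma_major, tolerance = 0.01)
  expect_equal(f1$sigma_minor, f2$sigma_minor, tolerance = 0.01)
  dtheta <- (f2$theta - f1$theta) %% pi
  expect_equal(min(abs(dtheta - pi / 2), abs(dtheta - pi / 2 - pi)), 0, tolerance = 0.02)
})

test_that("1D axial fit recovers sigma and fails on degenerate profiles", {
  zz <- 0:24
  prof <- 20 + 300 * exp(-(zz - 12.3)^2 / (2 * 3.5^2))
  fit <- fit_gaussian_1d(prof, init_sigma = 3)
  expect_identical(fit$status, "ok")
  expect_equal(fit$sigma_z, 3.5, tolerance = 0.01)
  expect_equal(fit$center_z, 12.3, tolerance = 0.01)
  expect_gt(fit$r_squared, 0.999)

  expect_identical(fit_gaussian_1d(rep(5, 10), 2)$status, "fit_failed")
  expect_error(fit_gaussian_1d(c(1, 2), 2), "5 axial samples")
})

test_that("FWHM unit duality: nm / px equals the pixel size for every feature", {
  st <- blob_stack(c(21, 41, 41), list(c(10, 14, 14), c(10, 28, 28)),
                   s_xy = 2, s_z = 2.5, amplitude = 400, background = 20,
                   dx = 40, dy = 40, dz = 100)
  pk <- exclude_close_peaks(find_peaks(build_scale_space(st)))
  m <- measure_features(st, pk, init_sigma = 2)
  ok <- m[m$status == "ok", ]
  expect_gt(nrow(ok), 0)
  expect_equal(ok$fwhm_max_nm / ok$fwhm_max_px, rep(40, nrow(ok)))
  expect_equal(ok$fwhm_z_nm / ok$fwhm_z_px, rep(100, nrow(ok)))
})

test_that("absent dz means axial FWHM is reported in pixels only", {
  st <- blob_stack(c(21, 33, 33), list(c(10, 16, 16)), s_xy = 2, s_z = 2.5,
                   amplitude = 400, background = 20, dx = 40, dy = 40, dz = NA)
  pk <- find_peaks(build_scale_space(st))
  m <- measure_features(st, pk, init_sigma = 2)
  expect_true(all(is.na(m$fwhm_z_nm)))
  expect_false(any(is.na(m$fwhm_z_px[m$status == "ok"])))
  expect_false(any(is.na(m$fwhm_x_nm[m$status == "ok"])))  # lateral still calibrated
})

test_that("field summary averages only ok fits and matches hand computation", {
  m <- tibble::tibble(
    index = 1:3, z = 5L, y = c(10L, 20L, 8L), x = c(10L, 20L, 25L),
    response = 1, cz = 5, cy = 10, cx = 10,
    sigma_major = 1, sigma_minor = 1, theta = 0, sigma_z = 2,
    amplitude = 10, offset = 1,
    fwhm_max_px = c(6, 8, NA), fwhm_min_px = c(5, 7, NA),
    fwhm_x_px = c(6, 8, NA), fwhm_y_px = c(5, 7, NA), fwhm_z_px = c(10, 12, NA),
    fwhm_max_nm = c(240, 320, NA), fwhm_min_nm = c(200, 280, NA),
    fwhm_x_nm = c(250, 300, NA), fwhm_y_nm = c(200, 280, NA),
    fwhm_z_nm = c(1000, 1200, NA),
    r2_xy = c(0.99, 0.98, NA), r2_z = c(0.99, 0.97, NA),
    status = c("ok", "ok", "fit_failed")
  )
  fs <- summarize_field(m)
  expect_identical(fs$n_ok, 2L)
  expect_identical(fs$n_failed, 1L)
  avg <- fs$averages
  expect_equal(avg$mean_nm[avg$parameter == "fwhm_x"], 275)
  expect_equal(avg$sd_nm[avg$parameter == "fwhm_x"], sd(c(250, 300)), tolerance = 1e-12)
  expect_equal(round(avg$sd_nm[avg$parameter == "fwhm_x"], 2), 35.36)

  one <- summarize_field(m[1, ])
  a1 <- one$averages
  expect_equal(a1$mean_nm[a1$parameter == "fwhm_x"], 250)
  expect_true(is.na(a1$sd_nm[a1$parameter == "fwhm_x"]))

  none <- summarize_field(m[m$status == "missing", ])
  expect_identical(none$n_ok, 0L)
  expect_true(all(is.na(none$averages$mean_nm)))
})

test_that("tidy and glance methods expose fit results as tibbles", {
  fit <- fit_gaussian_2d(gauss_patch(5, 2.5, 2), init_sigma = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 7L)
  gl <- glance(fit)
  expect_gt(gl$r_squared, 0.99)

  fit1 <- fit_gaussian_1d(10 + 100 * exp(-((0:20) - 10)^2 / 8), init_sigma = 2)
  expect_identical(nrow(tidy(fit1)), 4L)
  expect_identical(glance(fit1)$status, "ok")
})
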