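test_that("segment grid matches the brute-force inscribed-circle count", {
  cfg <- test_optics()
  lay <- build_segment_grid(cfg, 32)
  expect_identical(lay$M, 812L)
  expect_identical(lay$M, brute_inscribed_count(32))
  # N = 32 satisfies the pi/4 * N^2 area estimate to 2%
  expect_lt(abs(lay$M - pi / 4 * 32^2) / (pi / 4 * 32^2), 0.02)
  # area scaling between N = 16 and N = 64 follows the lattice count
  m16 <- build_segment_grid(cfg, 16)$M
  m64 <- build_segment_grid(cfg, 64)$M
  expect_identical(m16, brute_inscribed_count(16))
  expect_identical(m64, brute_inscribed_count(64))
  expect_lt(abs(m64 / m16 - 16) / 16, 0.035)
  expect_error(build_segment_grid(cfg, 33), "even")
  expect_error(build_segment_grid(cfg, 256), "too large")
})

test_that("active mask is symmetric under 90-degree rotation", {
  lay <- build_segment_grid(small_optics(), 4)
  rot <- t(apply(lay$active, 2, rev))
  expect_identical(unname(lay$active), unname(rot))
})

test_that("unaberrated focus hits the Airy FWHM calibration", {
  for (cfg in list(test_optics(),
                   optical_config(wavelength_um = 0.488, grid_n = 512,
                                  pupil_diameter_px = 256))) {
    pupil <- matrix(0 + 0i, cfg$grid_n, cfg$grid_n)
    pupil[fcoat:::pupil_mask(cfg)] <- 1
    img <- Mod(propagate_to_focus(pupil, cfg))^2
    up <- interpolate_image(img, 10)
    fw <- compute_fwhm(up, cfg$focal_pixel_pitch / 10)
    airy <- 0.514 * cfg$wavelength_um / cfg$na
    expect_lt(abs(fw[["mean"]] - airy) / airy, 0.05)
  }
})

test_that("shrinking the pupil five-fold widens the focus five-fold", {
  cfg1 <- test_optics()
  cfg5 <- optical_config(pupil_scale = 0.2)
  fw <- sapply(list(cfg1, cfg5), function(cfg) {
    pupil <- matrix(0 + 0i, cfg$grid_n, cfg$grid_n)
    pupil[fcoat:::pupil_mask(cfg)] <- 1
    img <- Mod(propagate_to_focus(pupil, cfg))^2
    compute_fwhm(interpolate_image(img, 10), cfg$focal_pixel_pitch / 10)[["mean"]]
  })
  expect_lt(abs(fw[2] / fw[1] - 5) / 5, 0.05)
})

test_that("propagation conserves energy and is linear", {
  cfg <- small_optics()
  set.seed(42)
  f <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  g <- propagate_to_focus(f, cfg)
  expect_lt(abs(sum(Mod(f)^2) - sum(Mod(g)^2)) / sum(Mod(f)^2), 1e-6)
  expect_equal(propagate_to_focus(matrix(0 + 0i, 64, 64), cfg),
               matrix(0 + 0i, 64, 64))
  f2 <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  expect_equal(propagate_to_focus(f + 2 * f2, cfg),
               g + 2 * propagate_to_focus(f2, cfg), tolerance = 1e-12)
})

test_that("segment-response basis reproduces direct propagation exactly", {
  cfg <- small_optics()
  lay <- build_segment_grid(cfg, 8)
  scr <- make_phase_screen(64, 2, 2 * pi, seed = 4)
  ap <- detection_aperture(cfg, radius_um = 2 * cfg$focal_pixel_pitch)
  basis <- precompute_segment_responses(lay, scr, cfg, ap, full_frame = TRUE)

  render_direct <- function(state) {
    n <- cfg$grid_n
    phase <- matrix(0, n, n)
    seg <- lay$pixel_seg
    phase[!is.na(seg)] <- state[seg[!is.na(seg)]]
    pupil <- matrix(0 + 0i, n, n)
    pupil[fcoat:::pupil_mask(cfg)] <- 1
    Mod(propagate_to_focus(pupil * scr$values * exp(1i * phase), cfg))^2
  }

  # flat state: sum of segment responses + static equals direct propagation
  flat <- rep(0, lay$M)
  expect_equal(render_focal_image(basis, flat), render_direct(flat),
               tolerance = 1e-12)
  # flipping one segment changes the full-frame field by exactly -2 E_i
  one <- flat; one[5] <- pi
  d_field <- basis$E_full %*% (exp(1i * one) - exp(1i * flat))
  expect_equal(as.vector(d_field), -2 * basis$E_full[, 5], tolerance = 1e-12)
  # 100 random binary states: detected intensity via basis vs direct render
  set.seed(7)
  ap_lin <- ap$pixels[, 1] + (ap$pixels[, 2] - 1) * cfg$grid_n
  for (k in 1:100) {
    st <- sample(c(0, pi), lay$M, replace = TRUE)
    direct <- sum(render_direct(st)[ap_lin])
    expect_lt(abs(detect_intensity(basis, st) - direct) / direct, 1e-9)
  }
})

test_that("detected intensity scales quadratically and rejects bad states", {
  lay <- bare_layout(4)
  med <- medium_from_row(c(1, 1i, -1, 2), n_out = 3)
  cfg <- small_optics()
  basis <- precompute_segment_responses(lay, med, cfg)
  st <- c(0, pi, 0, pi)
  i1 <- detect_intensity(basis, st)
  basis2 <- basis; basis2$E <- 2 * basis$E
  expect_equal(detect_intensity(basis2, st), 4 * i1)
  expect_error(detect_intensity(basis, c(0, pi)), "length")
  expect_error(detect_intensity(basis, c(0, pi, 1, 0)), "0 or pi")
  zero <- basis; zero$E[] <- 0
  expect_equal(detect_intensity(zero, st), 0)
})

test_that("matrix media plug into the basis with the aperture selecting rows", {
  lay <- bare_layout(6)
  m <- make_transmission_matrix(10, 6, seed = 2)
  cfg <- small_optics()
  basis <- precompute_segment_responses(lay, m, cfg, aperture = c(2L, 5L))
  st <- rep(0, 6)
  direct <- Mod(m$values %*% exp(1i * st))^2
  expect_equal(detect_intensity(basis, st), sum(direct[c(2, 5)]))
  full <- precompute_segment_responses(lay, m, cfg, full_frame = TRUE)
  expect_equal(render_focal_image(full, st), as.vector(direct))
  expect_error(render_focal_image(basis, st), "full_frame")
  expect_error(precompute_segment_responses(bare_layout(5), m, cfg), "n_in")
})

test_that("detection aperture always covers at least one pixel", {
  cfg <- test_optics()
  ap1 <- detection_aperture(cfg)
  expect_identical(nrow(ap1$pixels), 1L)
  c0 <- fcoat:::grid_center(cfg$grid_n)
  expect_equal(unname(ap1$pixels[1, ]), c(c0, c0))
  # off-grid centre still snaps to a pixel
  ap2 <- detection_aperture(cfg, center_um = c(0.7, -0.2), radius_um = 1e-6)
  expect_gte(nrow(ap2$pixels), 1L)
  ap3 <- detection_aperture(cfg, radius_um = 10)
  expect_gt(nrow(ap3$pixels), 100)
  ap4 <- detection_aperture(cfg, shape = "rectangle",
                            half_extents_um = c(5, 2))
  expect_gt(nrow(ap4$pixels), 10)
})
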