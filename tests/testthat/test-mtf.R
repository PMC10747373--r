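test_that("edge tilt is recovered from noiseless renders", {
  fx <- edge_fixture(n = 128, angle = 2)
  expect_equal(estimate_edge_angle(fx$img, fx$roi), 2, tolerance = 0.05)
  # aligned edge on a pixel border
  sc0 <- render_scene(scene_spec("edge", fluence = 100, edge_angle_deg = 0),
                      c(64, 64), 0.048)
  roi0 <- rect_roi(2, 12, 60, 40)
  expect_lt(abs(estimate_edge_angle(sc0, roi0)), 0.01)
  # and from a noisy exposure, to within a tenth of a degree
  det <- detector_preset("thin", seed = 21)
  noisy <- expose(render_scene(scene_spec("edge", fluence = 400,
                                          edge_angle_deg = 2),
                               c(256, 256), 0.048), det)
  roi <- rect_roi(8, 88, 240, 80)
  expect_equal(estimate_edge_angle(noisy, roi), 2, tolerance = 0.1)
})

test_that("images without an edge are rejected", {
  flat <- raster_image(matrix(100, 64, 64), 0.048)
  expect_error(estimate_edge_angle(flat, rect_roi(2, 2, 60, 60)),
               "detectable edge")
  noisy <- noisy_flat(64, seed = 22)
  expect_error(estimate_edge_angle(noisy, rect_roi(2, 2, 60, 60)),
               "detectable edge")
})

test_that("a noiseless area-fraction edge reproduces the aperture MTF", {
  fx <- edge_fixture(n = 128, angle = 2, fluence = 100)
  m <- compute_mtf(fx$img, fx$roi, oversample = 4)
  expect_identical(m$mtf[1], 1)
  nyq <- 1 / (2 * 0.048)
  f <- m$freq[m$freq > 0 & m$freq <= 0.8 * nyq]
  aperture <- abs(sinc_oracle(pi * f * 0.048))
  got <- stats::approx(m$freq, m$mtf, f)$y
  expect_lt(max(abs(got - aperture) / aperture), 0.02)
})

test_that("a Gaussian-blurred edge reproduces the transfer-function product", {
  fx <- edge_fixture(n = 160, angle = 2, fluence = 100)
  sigma_mm <- 0.05
  blurred <- raster_image(
    scintopt:::gaussian_blur(fx$img$pixels, sigma_mm / 0.048), 0.048)
  m <- compute_mtf(blurred, fx$roi, oversample = 4)
  nyq <- 1 / (2 * 0.048)
  f <- m$freq[m$freq > 0 & m$freq <= 0.8 * nyq]
  oracle <- exp(-2 * pi^2 * sigma_mm^2 * f^2) * abs(sinc_oracle(pi * f * 0.048))
  got <- stats::approx(m$freq, m$mtf, f)$y
  expect_lt(max(abs(got - oracle) / oracle), 0.05)
})

test_that("MTF is invariant to the exact edge tilt", {
  m15 <- with(edge_fixture(160, 1.5), compute_mtf(img, roi))
  m30 <- with(edge_fixture(160, 3.0), compute_mtf(img, roi))
  nyq <- 1 / (2 * 0.048)
  f <- seq(0.2, 0.8 * nyq, length.out = 40)
  a <- stats::approx(m15$freq, m15$mtf, f)$y
  b <- stats::approx(m30$freq, m30$mtf, f)$y
  expect_lt(sqrt(mean((a - b)^2)), 0.03)
})

test_that("the 10%-MTF frequency falls strictly with scintillator blur", {
  f10_at <- function(sigma_mm) {
    det <- detector_config(psf_sigma_mm = sigma_mm, gain = 40, read_noise = 8,
                           seed = 23)
    sc <- render_scene(scene_spec("edge", fluence = 400, edge_angle_deg = 2),
                       c(256, 256), 0.048)
    compute_mtf(expose(sc, det), rect_roi(8, 88, 240, 80))$f10
  }
  f10s <- vapply(c(0.04, 0.06, 0.09), f10_at, 0)
  expect_true(all(diff(f10s) < 0))
})

test_that("thick-preset exposures resolve less than thin-preset exposures", {
  sc <- render_scene(scene_spec("edge", fluence = 400, edge_angle_deg = 2),
                     c(256, 256), 0.048)
  roi <- rect_roi(8, 88, 240, 80)
  f_thin <- compute_mtf(expose(sc, detector_preset("thin", seed = 24)), roi)$f10
  f_thick <- compute_mtf(expose(sc, detector_preset("thick", seed = 25)), roi)$f10
  expect_lt(f_thick, f_thin)
})

test_that("oversample and tilt contracts are enforced", {
  fx <- edge_fixture(n = 128, angle = 2)
  expect_error(compute_mtf(fx$img, fx$roi, oversample = 3), "4 or 8")
  m8 <- compute_mtf(fx$img, fx$roi, oversample = 8)
  expect_identical(m8$esf_oversample, 8L)
  # an untilted edge leaves most oversampled bins empty
  sc0 <- render_scene(scene_spec("edge", fluence = 100, edge_angle_deg = 0),
                      c(64, 64), 0.048)
  expect_error(compute_mtf(sc0, rect_roi(2, 12, 60, 40)), "empty")
})
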