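test_that("flat and aligned-edge scenes render exactly", {
  flat <- render_scene(scene_spec("flat", fluence = 100), c(8, 8), 0.048)
  expect_true(all(flat$pixels == 100))

  # edge at 0 degrees with the boundary on a pixel border: a pure step
  sc <- render_scene(scene_spec("edge", fluence = 100, edge_angle_deg = 0),
                     c(16, 16), 0.048)
  expect_true(all(sc$pixels[, 1:8] == 0))
  expect_true(all(sc$pixels[, 9:16] == 100))
})

test_that("tilted-edge boundary pixels carry exact geometric area fractions", {
  angle <- atan(1 / 20) * 180 / pi        # slope 1/20
  n <- 64L
  sc <- render_scene(scene_spec("edge", fluence = 100, edge_angle_deg = angle),
                     c(n, n), 0.048)
  s <- 1 / 20
  # line x = n/2 + s * (y - n/2); bright half-plane x - s*y - (n/2)(1 - s) >= 0
  withr::with_seed(42, {
    rows <- sample(n, 10)
    for (r in rows) {
      cb <- round(n / 2 + s * (r - 0.5 - n / 2)) # a boundary-adjacent column
      for (cc in (cb - 1L):(cb + 1L)) {
        area <- halfplane_clip_area(cc - 1, cc, r - 1, r,
                                    1, -s, -(n / 2) * (1 - s))
        expect_equal(sc$pixels[r, cc], 100 * area, tolerance = 1e-12)
      }
    }
  })
})

test_that("line-pair scenes honor Nyquist and reject offending groups", {
  sp <- scene_spec("line_pairs", fluence = 100,
                   line_groups = list(c(2, 1), c(5, 0.5)))
  img <- render_scene(sp, c(64, 128), 0.048)
  expect_equal(dim(img$pixels), c(64L, 128L))
  expect_true(all(img$pixels >= 0 & img$pixels <= 100))
  bad <- scene_spec("line_pairs", fluence = 100,
                    line_groups = list(c(2, 1), c(12, 1)))
  expect_error(render_scene(bad, c(64, 128), 0.048), "12")
})

test_that("exposure follows the Poisson high-count limit", {
  det <- detector_config(psf_sigma_mm = 0, gain = 1e6, read_noise = 0,
                         bit_depth = 32L, seed = 3L)
  flat <- render_scene(scene_spec("flat", fluence = 1), c(16, 16), 0.048)
  ex <- expose(flat, det)
  expect_lt(max(abs(ex$pixels - 1e6) / 1e6), 0.01)
})

test_that("exposure noise is Poisson: variance tracks the mean", {
  det <- detector_config(psf_sigma_mm = 0, gain = 40, read_noise = 0, seed = 5L)
  flat <- render_scene(scene_spec("flat", fluence = 100), c(512, 512), 0.048)
  ex <- expose(flat, det)
  v <- as.vector(ex$pixels)
  expect_equal(stats::var(v), mean(v), tolerance = 0.05)
})

test_that("thin preset is noisier than thick on an identical flat scene", {
  flat <- render_scene(scene_spec("flat", fluence = 400), c(128, 128), 0.048)
  roi <- rect_roi(8, 8, 112, 112)
  snr_thin <- roi_snr(expose(flat, detector_preset("thin", seed = 1)), roi)
  snr_thick <- roi_snr(expose(flat, detector_preset("thick", seed = 2)), roi)
  expect_lt(snr_thin, snr_thick)
  expect_lt(detector_preset("thin")$psf_sigma_mm,
            detector_preset("thick")$psf_sigma_mm)
})

test_that("exposure and flat stacks are deterministic in the seed", {
  det <- detector_preset("thin", seed = 11L)
  flat <- render_scene(scene_spec("flat", fluence = 400), c(32, 32), 0.048)
  expect_identical(expose(flat, det)$pixels, expose(flat, det)$pixels)
  s1 <- make_flat_stack(det, 4, 400, c(32, 32))
  s2 <- make_flat_stack(det, 4, 400, c(32, 32))
  for (i in 1:4) expect_identical(s1$frames[[i]]$pixels, s2$frames[[i]]$pixels)
  # frames within a stack are distinct noise realizations
  expect_false(identical(s1$frames[[1]]$pixels, s1$frames[[2]]$pixels))
})

test_that("flat stacks need >= 2 frames and vanish in the noiseless limit", {
  det <- detector_preset("thin")
  expect_error(make_flat_stack(det, 1), ">= 2")
  hi <- detector_config(psf_sigma_mm = 0, gain = 1e9, read_noise = 0,
                        bit_depth = 32L, seed = 1L)
  st <- make_flat_stack(hi, 2, 1, c(16, 16))
  rel <- abs(st$frames[[1]]$pixels - st$frames[[2]]$pixels) / 1e9
  expect_lt(max(rel), 1e-3)
})

test_that("per-pixel frame means satisfy the Poisson z-score bound", {
  det <- detector_config(psf_sigma_mm = 0, gain = 40, read_noise = 0, seed = 7L)
  st <- make_flat_stack(det, 16, 100, c(64, 64))
  mu <- 40 * 100
  m <- Reduce(`+`, lapply(st$frames, `[[`, "pixels")) / 16
  z <- (m - mu) / (sqrt(mu) / sqrt(16))
  expect_gte(mean(abs(z) < 3), 0.99)
})

test_that("flat-field NNPS amplitude scales as 1/gain at fixed fluence", {
  mk <- function(g) {
    det <- detector_config(psf_sigma_mm = 0, gain = g, read_noise = 0, seed = 9L)
    st <- make_flat_stack(det, 16, 400, c(128, 128))
    r <- nnps_2d(st, roi_size = 64, overlap = 0.5)
    m <- r$nnps2d; m[33, 33] <- NA           # drop DC
    mean(m, na.rm = TRUE)
  }
  ratio <- mk(25) / mk(100)
  expect_equal(ratio, 4, tolerance = 0.15)
})
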