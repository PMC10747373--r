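mk_result <- function(h, epi, snr, spacing = "linear") {
  structure(list(h_grid = h, epi_curve = epi, snr_norm_curve = snr,
                 grid_spacing = spacing),
            class = "sweep_result")
}

test_that("crossing selection reproduces hand-computed examples", {
  # exact tie at a grid point
  r <- mk_result(c(0.001, 0.0255, 0.05, 0.0745, 0.1),
                 c(1.0, 0.75, 0.5, 0.25, 0.0),
                 c(0.0, 0.25, 0.5, 0.75, 1.0))
  sel <- select_optimal_h(r)
  expect_identical(sel$status, "crossed")
  expect_identical(sel$optimal_h, 0.05)
  expect_identical(sel$crossing_index, 3L)
  # linear interpolation between grid points
  r2 <- mk_result(c(0.01, 0.02), c(0.8, 0.6), c(0.5, 0.7))
  sel2 <- select_optimal_h(r2)
  expect_equal(sel2$optimal_h, 0.0175, tolerance = 1e-15)
  # no sign change
  r3 <- mk_result(c(0.01, 0.02, 0.03), c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
  expect_identical(select_optimal_h(r3)$status, "no_crossing")
  expect_true(is.na(select_optimal_h(r3)$optimal_h))
})

test_that("log-grid interpolation works in log10(h)", {
  r <- mk_result(c(0.01, 0.1), c(0.6, 0.2), c(0.4, 0.4), spacing = "log")
  sel <- select_optimal_h(r)
  # d = [0.2, -0.2]: midpoint in log space
  expect_equal(sel$optimal_h, 10^mean(log10(c(0.01, 0.1))), tolerance = 1e-12)
})

test_that("sweep configuration validates its ROIs and grid", {
  a <- rect_roi(0, 0, 10, 10); b <- rect_roi(0, 20, 10, 10)
  expect_error(sweep_config(h_min = 0.1, h_max = 0.01, epi_roi = a, snr_roi = b),
               "h_min")
  expect_error(sweep_config(n_steps = 2, epi_roi = a, snr_roi = b), "n_steps")
  expect_error(sweep_config(epi_roi = a, snr_roi = rect_roi(5, 5, 10, 10)),
               "disjoint")
})

test_that("a noiseless pair raises the homogeneous-ROI error during the sweep", {
  pair <- simulate_study_pair(seed = 1, shape = c(64, 64))
  cfg <- sweep_config(n_steps = 3, epi_roi = pair$epi_roi,
                      snr_roi = pair$snr_roi)
  expect_error(run_sweep(pair$scene, pair$scene, cfg), "homogeneous")
})

test_that("the sweep is deterministic and its crossing is bracketed", {
  pair <- simulate_study_pair(seed = 2, shape = c(96, 128))
  cfg <- sweep_config(n_steps = 12, epi_roi = pair$epi_roi,
                      snr_roi = pair$snr_roi)
  res1 <- run_sweep(pair$thin, pair$thick, cfg)
  res2 <- run_sweep(pair$thin, pair$thick, cfg)
  expect_identical(res1, res2)
  expect_identical(res1$status, "crossed")
  i <- res1$crossing_index
  expect_gte(res1$optimal_h, res1$h_grid[i])
  expect_lte(res1$optimal_h, res1$h_grid[i + 1])
  # re-evaluating both curves exactly at the interpolated h stays within the
  # larger adjacent grid gap of the crossing value
  p <- res1$nlm; p$h <- res1$optimal_h
  nl <- nlm_denoise(pair$thin, p)
  e <- epi(pair$thin, nl, cfg$epi_roi)
  s <- roi_snr(nl, cfg$snr_roi) / roi_snr(pair$thick, cfg$snr_roi)
  gap <- max(abs(res1$epi_curve[i + 1] - res1$epi_curve[i]),
             abs(res1$snr_norm_curve[i + 1] - res1$snr_norm_curve[i]))
  expect_lt(abs(e - s), gap)
})

test_that("grid refinement moves the optimum by less than a coarse interval", {
  pair <- simulate_study_pair(seed = 3, shape = c(96, 128))
  coarse <- sweep_config(n_steps = 12, epi_roi = pair$epi_roi,
                         snr_roi = pair$snr_roi)
  fine <- sweep_config(n_steps = 24, epi_roi = pair$epi_roi,
                       snr_roi = pair$snr_roi)
  rc <- run_sweep(pair$thin, pair$thick, coarse)
  rf <- run_sweep(pair$thin, pair$thick, fine)
  i <- rc$crossing_index
  interval <- rc$h_grid[i + 1] - rc$h_grid[i]
  expect_lt(abs(rf$optimal_h - rc$optimal_h), interval)
})

test_that("apply_optimal delegates exactly and improves on both endpoints", {
  pair <- simulate_study_pair(seed = 4, shape = c(96, 128))
  cfg <- sweep_config(n_steps = 12, epi_roi = pair$epi_roi,
                      snr_roi = pair$snr_roi)
  res <- run_sweep(pair$thin, pair$thick, cfg)
  out <- apply_optimal(pair$thin, res)
  p <- res$nlm; p$h <- res$optimal_h
  expect_identical(out$pixels, nlm_denoise(pair$thin, p)$pixels)
  # smoothing at h* raises SNR over the raw thin image
  expect_gt(roi_snr(out, cfg$snr_roi), roi_snr(pair$thin, cfg$snr_roi))
  # and preserves more edge than smoothing at h_max
  p_max <- res$nlm; p_max$h <- max(res$h_grid)
  at_max <- nlm_denoise(pair$thin, p_max)
  expect_gt(epi(pair$thin, out, cfg$epi_roi),
            epi(pair$thin, at_max, cfg$epi_roi))
  # no crossing -> refusal
  bad <- res; bad$status <- "no_crossing"
  expect_error(apply_optimal(pair$thin, bad), "crossing")
})
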