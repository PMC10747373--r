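#' Detector configuration for the simulated scintillator + sensor chain
#'
#' The scintillator is modeled as a Gaussian point-spread function followed by
#' a quantum gain stage, Poisson sampling, additive Gaussian read noise and
#' quantization. Scintillator thickness is represented operationally: a
#' thicker screen converts more X-rays to light (higher gain, cleaner image)
#' but spreads the light further (wider PSF, blurrier image).
#'
#' @param psf_sigma_mm Gaussian scintillator-blur standard deviation (mm, >= 0).
#' @param gain expected detected quanta per unit incident fluence (> 0).
#' @param read_noise additive Gaussian noise standard deviation (counts, >= 0).
#' @param pixel_pitch_mm sampling pitch (mm, > 0).
#' @param bit_depth output quantization depth in bits.
#' @param seed integer RNG seed; all simulator outputs are pure functions of
#'   their inputs and this seed.
#' @return a `detector_config` object.
#' @export
detector_config <- function(psf_sigma_mm, gain, read_noise = 8,
                            pixel_pitch_mm = 0.048, bit_depth = 16L,
                            seed = 1L) {
  if (psf_sigma_mm < 0) stop("psf_sigma_mm must be >= 0", call. = FALSE)
  if (gain <= 0) stop("gain must be > 0", call. = FALSE)
  if (read_noise < 0) stop("read_noise must be >= 0", call. = FALSE)
  if (pixel_pitch_mm <= 0) stop("pixel_pitch_mm must be > 0", call. = FALSE)
  if (bit_depth < 1 || bit_depth > 32) stop("bit_depth out of range", call. = FALSE)
  structure(list(psf_sigma_mm = psf_sigma_mm, gain = gain,
                 read_noise = read_noise, pixel_pitch_mm = pixel_pitch_mm,
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
            class = "detector_config")
}

#' Named detector presets emulating thin and thick scintillators
#'
#' `"thin"` stands in for a 96 um screen (sharper, noisier), `"thick"` for a
#' 140 um screen (blurrier, cleaner). Both share the 48 um pitch and 16-bit
#' depth of the emulated CMOS sensor; blur and gain values are package
#' calibration choices reproducing the qualitative thin/thick ordering, not
#' physical measurements.
#'
#' @param name `"thin"` or `"thick"`.
#' @param seed RNG seed forwarded to [detector_config()].
#' @return a `detector_config`.
#' @export
detector_preset <- function(name = c("thin", "thick"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    thin  = detector_config(psf_sigma_mm = 0.040, gain = 40,  read_noise = 8,
                            pixel_pitch_mm = 0.048, bit_depth = 16L, seed = seed),
    thick = detector_config(psf_sigma_mm = 0.060, gain = 100, read_noise = 8,
                            pixel_pitch_mm = 0.048, bit_depth = 16L, seed = seed))
}

#' Ideal scene specification
#'
#' @param kind one of `"flat"`, `"line_pairs"`, `"edge"`.
#' @param fluence mean incident intensity (arbitrary units, > 0). The default
#'   of 400 puts the flat-field mean of both presets in the interior of the
#'   16-bit range (thin ~16000, thick ~40000 counts) with no clipping.
#' @param line_groups for `kind = "line_pairs"`: a list of `c(frequency_lp_mm,
#'   contrast)` pairs; frequencies must be below Nyquist.
#' @param edge_angle_deg for `kind = "edge"`: tilt of the edge from vertical,
#'   in degrees, `0 < angle <= 10` (the slanted-edge MTF contract needs a
#'   small tilt).
#' @param edge_contrast ratio of dark to bright side, in `(0, 1]` where 1
#'   means a fully dark left side (dark level = (1 - contrast) * fluence).
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(kind = c("flat", "line_pairs", "edge"), fluence = 400,
                       line_groups = NULL, edge_angle_deg = 2,
                       edge_contrast = 1) {
  kind <- match.arg(kind)
  if (fluence <= 0) stop("fluence must be > 0", call. = FALSE)
  if (kind == "edge") {
    if (edge_angle_deg < 0 || edge_angle_deg > 10)
      stop("edge_angle_deg must be in [0, 10]", call. = FALSE)
    if (edge_contrast <= 0 || edge_contrast > 1)
      stop("edge_contrast must be in (0, 1]", call. = FALSE)
  }
  if (kind == "line_pairs") {
    if (is.null(line_groups) || !length(line_groups))
      stop("line_groups required for kind = 'line_pairs'", call. = FALSE)
    for (g in line_groups)
      if (length(g) != 2L || g[1] <= 0 || g[2] <= 0 || g[2] > 1)
        stop("each line group must be c(frequency > 0, contrast in (0,1])",
             call. = FALSE)
  }
  structure(list(kind = kind, fluence = fluence, line_groups = line_groups,
                 edge_angle_deg = edge_angle_deg, edge_contrast = edge_contrast),
            class = "scene_spec")
}

#' Render a noiseless ideal scene
#'
#' `flat` renders a constant field; `line_pairs` renders horizontal bands of
#' vertical square-wave bar patterns, one band per group; `edge` renders a
#' two-level step whose boundary is tilted from vertical, with sub-pixel
#' boundary pixels set to the exact geometric bright-area fraction (so the
#' rendered edge has an analytic pixel-aperture MTF).
#'
#' @param spec a [scene_spec()].
#' @param shape `c(rows, cols)` in pixels.
#' @param pitch_mm pixel pitch (mm), used for Nyquist validation and attached
#'   to the output.
#' @return a noiseless [raster_image()] in fluence units.
#' @export
render_scene <- function(spec, shape = c(512L, 1024L), pitch_mm = 0.048) {
  if (!inherits(spec, "scene_spec")) stop("`spec` must be a scene_spec", call. = FALSE)
  if (length(shape) != 2L || any(shape < 2))
    stop("`shape` must be two positive extents", call. = FALSE)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  px <- switch(spec$kind,
    flat = matrix(spec$fluence, nr, nc),
    line_pairs = render_line_pairs(spec, nr, nc, pitch_mm),
    edge = render_edge(spec, nr, nc))
  raster_image(px, pitch_mm, value_range = c(0, max(px)))
}

render_line_pairs <- function(spec, nr, nc, pitch_mm) {
  nyq <- 1 / (2 * pitch_mm)
  for (g in spec$line_groups)
    if (g[1] >= nyq)
      stop(sprintf("line group at %.3g lp/mm is at or above Nyquist (%.3g lp/mm)",
                   g[1], nyq), call. = FALSE)
  px <- matrix(spec$fluence, nr, nc)
  n_groups <- length(spec$line_groups)
  band_h <- nr %/% n_groups
  x_mm <- (seq_len(nc) - 0.5) * pitch_mm
  for (i in seq_len(n_groups)) {
    g <- spec$line_groups[[i]]
    # square wave: bright/dark bars, one line pair per 1/f mm
    bar <- ifelse((floor(2 * g[1] * x_mm) %% 2) == 0, 1, 1 - g[2])
    r0 <- (i - 1L) * band_h + 1L
    r1 <- if (i == n_groups) nr else i * band_h
    px[r0:r1, ] <- rep(spec$fluence * bar, each = r1 - r0 + 1L)
  }
  px
}

# Exact area-fraction step: the boundary line passes through the image centre
# with slope tan(angle) (columns per row); pixels right of the line are
# bright. Pixel (r, c) covers rows [r-1, r] x cols [c-1, c] in continuous
# 0-based coordinates.
render_edge <- function(spec, nr, nc) {
  bright <- spec$fluence
  dark <- (1 - spec$edge_contrast) * spec$fluence
  s <- tan(spec$edge_angle_deg * pi / 180)   # d(col)/d(row)
  col_mid <- nc / 2
  px <- matrix(dark, nr, nc)
  cols <- seq_len(nc)
  for (r in seq_len(nr)) {
    # boundary column at pixel-row top (y = r - 1) and bottom (y = r);
    # bright fraction = mean over the pixel's rows of clamp(c - x(y), 0, 1)
    xt <- col_mid + s * ((r - 1) - nr / 2)
    xb <- col_mid + s * (r - nr / 2)
    f <- clamped_linear_mean(cols - xt, cols - xb)
    px[r, ] <- dark + f * (bright - dark)
  }
  px
}

#' Expose a noiseless scene through the detector chain
#'
#' Pipeline order is fixed: (1) Gaussian PSF blur (`psf_sigma_mm` converted to
#' pixels via the pitch, reflective boundaries); (2) multiply by `gain`;
#' (3) per-pixel Poisson sampling; (4) additive zero-mean Gaussian read noise;
#' (5) clip to `[0, 2^bit_depth - 1]` and round to integer counts. The same
#' seed and inputs give bit-identical output.
#'
#' @param scene noiseless [raster_image()], nonnegative, in fluence units.
#' @param det a [detector_config()].
#' @param seed optional override of `det$seed`.
#' @return a [raster_image()] of integer detector counts.
#' @export
expose <- function(scene, det, seed = det$seed) {
  assert_raster(scene)
  if (!inherits(det, "detector_config"))
    stop("`det` must be a detector_config", call. = FALSE)
  if (any(scene$pixels < 0)) stop("scene must be nonnegative", call. = FALSE)
  sigma_px <- det$psf_sigma_mm / det$pixel_pitch_mm
  lambda <- gaussian_blur(scene$pixels, sigma_px) * det$gain
  lambda[lambda < 0] <- 0    # guard tiny negative convolution residue
  vmax <- 2^det$bit_depth - 1
  counts <- withr::with_seed(seed, {
    n <- length(lambda)
    y <- stats::rpois(n, lambda)
    if (det$read_noise > 0) y <- y + stats::rnorm(n, 0, det$read_noise)
    y
  })
  counts <- matrix(pmin(pmax(round(counts), 0), vmax), nrow(lambda), ncol(lambda))
  raster_image(counts, det$pixel_pitch_mm, value_range = c(0, vmax))
}

#' Simulate a stack of flat-field ("white") exposures
#'
#' Frames are independent exposures of the same flat scene differing only in
#' the noise realization; the frame seeds derive deterministically from
#' `det$seed` plus the frame index, so the same configuration always yields
#' the identical stack.
#'
#' @param det a [detector_config()].
#' @param n_frames number of frames (>= 2; the NNPS ensemble average needs at
#'   least two).
#' @param fluence mean incident intensity of the flat scene.
#' @param shape image dimensions `c(rows, cols)`.
#' @return a `flat_field_stack`: list with `frames` (list of raster_image)
#'   and `pixel_pitch_mm`.
#' @export
make_flat_stack <- function(det, n_frames = 16L, fluence = 400,
                            shape = c(512L, 1024L)) {
  if (!inherits(det, "detector_config"))
    stop("`det` must be a detector_config", call. = FALSE)
  if (n_frames < 2) stop("n_frames must be >= 2", call. = FALSE)
  scene <- render_scene(scene_spec("flat", fluence = fluence), shape,
                        det$pixel_pitch_mm)
  frames <- lapply(seq_len(n_frames), function(i)
    expose(scene, det, seed = det$seed + i))
  flat_field_stack(frames)
}

#' Bundle same-shape frames into a flat-field stack
#'
#' @param frames list of [raster_image()] with identical shape and pitch.
#' @return a `flat_field_stack`.
#' @export
flat_field_stack <- function(frames) {
  if (length(frames) < 2L) stop("a flat-field stack needs >= 2 frames", call. = FALSE)
  lapply(frames, assert_raster)
  d <- dim(frames[[1]]$pixels)
  p <- frames[[1]]$pixel_pitch_mm
  for (f in frames)
    if (!identical(dim(f$pixels), d) || !identical(f$pixel_pitch_mm, p))
      stop("all frames must share shape and pitch", call. = FALSE)
  structure(list(frames = frames, pixel_pitch_mm = p),
            class = "flat_field_stack")
}

#' Simulate a matched thin/thick detector image pair for the h sweep
#'
#' Renders one tilted-edge scene and exposes it through both detector
#' presets, so the pair differs only in blur and noise — the situation the
#' smoothing-factor optimization assumes (one sharp noisy image, one blurry
#' clean image of the same object). Also returns ready-made ROIs: an
#' edge-spanning region for the edge preservation index and a disjoint
#' homogeneous region on the bright side for the SNR.
#'
#' @param seed base RNG seed; the thin and thick exposures use `seed` and
#'   `seed + 1000` so their noise realizations are independent.
#' @param shape image dimensions, default `c(512, 1024)` (the emulated
#'   sensor matrix).
#' @param fluence flat fluence of the bright side, default 400.
#' @param edge_angle_deg edge tilt, default 2 degrees.
#' @return list with `thin`, `thick` ([raster_image()]s), `scene`,
#'   `epi_roi`, `snr_roi`, `mtf_roi` ([rect_roi()]s).
#' @export
simulate_study_pair <- function(seed = 1L, shape = c(512L, 1024L),
                                fluence = 400, edge_angle_deg = 2) {
  spec <- scene_spec("edge", fluence = fluence,
                     edge_angle_deg = edge_angle_deg, edge_contrast = 1)
  det_thin <- detector_preset("thin", seed = seed)
  det_thick <- detector_preset("thick", seed = seed + 1000L)
  scene <- render_scene(spec, shape, det_thin$pixel_pitch_mm)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  # the edge runs near the centre column, excursing by nr * tan(angle)/2 on
  # either side; the EPI ROI straddles it and the SNR ROI sits fully on the
  # bright side, disjoint from it
  span <- as.integer(ceiling(nr * tan(edge_angle_deg * pi / 180))) + 8L
  r0 <- nr %/% 8L
  rh <- nr - 2L * r0
  ew <- min(2L * span + 48L, nc %/% 2L)
  epi_roi <- rect_roi(r0, nc %/% 2L - ew %/% 2L, rh, ew)
  snr_c0 <- max(nc %/% 2L + span + 4L, nc %/% 2L + ew %/% 2L + 4L)
  snr_w <- nc - snr_c0 - 4L
  if (snr_w < 8L)
    stop("image too narrow to place disjoint EPI and SNR ROIs", call. = FALSE)
  snr_roi <- rect_roi(r0, snr_c0, rh, snr_w)
  list(thin = expose(scene, det_thin),
       thick = expose(scene, det_thick),
       scene = scene, epi_roi = epi_roi, snr_roi = snr_roi,
       mtf_roi = epi_roi)
}

#' @export
print.flat_field_stack <- function(x, ...) {
  d <- dim(x$frames[[1]]$pixels)
  cat(sprintf("<flat_field_stack> %d frames of %d x %d px, pitch %.4g mm\n",
              length(x$frames), d[1], d[2], x$pixel_pitch_mm))
  invisible(x)
}
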