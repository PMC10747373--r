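#' Configuration of the smoothing-factor sweep
#'
#' @param h_min,h_max endpoints of the smoothing-factor grid on the
#'   normalized intensity scale; defaults `1e-3` and `1e-1`.
#' @param n_steps grid size (>= 3); default 100.
#' @param grid_spacing `"log"` (default; the two-decade default range calls
#'   for uniform resolution per decade) or `"linear"`.
#' @param epi_roi [rect_roi()] over an edge-bearing region: the sharpness
#'   tracking region.
#' @param snr_roi [rect_roi()] over a homogeneous region: the noise tracking
#'   region. Must be disjoint from `epi_roi`.
#' @param nlm an [nlm_params()] carrying patch and window radii (its `h` is
#'   overridden at every step).
#' @return a `sweep_config`.
#' @export
sweep_config <- function(h_min = 1e-3, h_max = 1e-1, n_steps = 100L,
                         grid_spacing = c("log", "linear"),
                         epi_roi, snr_roi, nlm = nlm_params()) {
  grid_spacing <- match.arg(grid_spacing)
  if (!(h_min > 0 && h_min < h_max))
    stop("need 0 < h_min < h_max", call. = FALSE)
  if (n_steps < 3) stop("n_steps must be >= 3", call. = FALSE)
  if (!inherits(epi_roi, "rect_roi") || !inherits(snr_roi, "rect_roi"))
    stop("epi_roi and snr_roi must be rect_roi objects", call. = FALSE)
  if (rois_overlap(epi_roi, snr_roi))
    stop("epi_roi and snr_roi must be disjoint", call. = FALSE)
  if (!inherits(nlm, "nlm_params")) stop("`nlm` must be nlm_params", call. = FALSE)
  structure(list(h_min = h_min, h_max = h_max, n_steps = as.integer(n_steps),
                 grid_spacing = grid_spacing, epi_roi = epi_roi,
                 snr_roi = snr_roi, nlm = nlm),
            class = "sweep_config")
}

rois_overlap <- function(a, b) {
  a$row0 < b$row0 + b$height && b$row0 < a$row0 + a$height &&
    a$col0 < b$col0 + b$width && b$col0 < a$col0 + a$width
}

sweep_grid <- function(cfg) {
  if (cfg$grid_spacing == "log")
    10^seq(log10(cfg$h_min), log10(cfg$h_max), length.out = cfg$n_steps)
  else
    seq(cfg$h_min, cfg$h_max, length.out = cfg$n_steps)
}

#' Sweep the NLM smoothing factor and trace EPI and normalized SNR
#'
#' For every smoothing factor h on the grid, the thin-detector image is
#' NLM-denoised; the edge preservation index is computed against the thin
#' image itself (the sharpness reference), and the ROI SNR of the denoised
#' image is normalized by the ROI SNR of the thick-detector image (bringing
#' it onto the same unit scale as the EPI: 1 means "as clean as the thick
#' detector"). The two curves start with EPI near 1 and normalized SNR well
#' below 1; as h grows the EPI falls and the normalized SNR rises, and
#' their crossing is selected as the optimal smoothing factor by
#' [select_optimal_h()].
#'
#' @param thin thin-detector (sharp, noisy) [raster_image()].
#' @param thick thick-detector (blurry, clean) [raster_image()] of the same
#'   shape and pitch.
#' @param cfg a [sweep_config()].
#' @return a `sweep_result`: `h_grid`, `epi_curve`, `snr_norm_curve`,
#'   `crossing_index`, `optimal_h`, `status` (`"crossed"` or
#'   `"no_crossing"`), `grid_spacing`, and the two ROIs.
#' @export
run_sweep <- function(thin, thick, cfg) {
  assert_raster(thin); assert_raster(thick)
  if (!inherits(cfg, "sweep_config")) stop("`cfg` must be a sweep_config", call. = FALSE)
  if (!identical(dim(thin$pixels), dim(thick$pixels)) ||
      thin$pixel_pitch_mm != thick$pixel_pitch_mm)
    stop("thin and thick images must share shape and pitch", call. = FALSE)
  check_roi(cfg$epi_roi, thin, "epi_roi")
  check_roi(cfg$snr_roi, thin, "snr_roi")
  snr_thick <- roi_snr(thick, cfg$snr_roi)
  if (snr_thick == 0) stop("thick-image SNR is zero", call. = FALSE)
  hs <- sweep_grid(cfg)
  n <- length(hs)
  epi_curve <- numeric(n)
  snr_curve <- numeric(n)
  for (i in seq_len(n)) {
    par_i <- cfg$nlm; par_i$h <- hs[i]
    nl <- tryCatch(nlm_denoise(thin, par_i), error = function(e)
      stop(sprintf("sweep step %d (h = %.4g): %s", i, hs[i],
                   conditionMessage(e)), call. = FALSE))
    epi_curve[i] <- tryCatch(epi(thin, nl, cfg$epi_roi), error = function(e)
      stop(sprintf("sweep step %d (h = %.4g): %s", i, hs[i],
                   conditionMessage(e)), call. = FALSE))
    snr_curve[i] <- tryCatch(roi_snr(nl, cfg$snr_roi) / snr_thick,
                             error = function(e)
      stop(sprintf("sweep step %d (h = %.4g): %s", i, hs[i],
                   conditionMessage(e)), call. = FALSE))
  }
  res <- structure(list(h_grid = hs, epi_curve = epi_curve,
                        snr_norm_curve = snr_curve,
                        crossing_index = NA_integer_, optimal_h = NA_real_,
                        status = "no_crossing",
                        grid_spacing = cfg$grid_spacing,
                        epi_roi = cfg$epi_roi, snr_roi = cfg$snr_roi,
                        nlm = cfg$nlm),
                   class = "sweep_result")
  sel <- select_optimal_h(res)
  res$crossing_index <- sel$crossing_index
  res$optimal_h <- sel$optimal_h
  res$status <- sel$status
  res
}

#' Select the crossing of the EPI and normalized-SNR curves
#'
#' With `d(i) = epi_curve[i] - snr_norm_curve[i]`: an exact zero at a grid
#' point selects that h (first such point); otherwise the first sign change
#' `d(i) * d(i+1) < 0` is linearly interpolated to `d = 0` — in `log10(h)`
#' on a log grid, in `h` on a linear grid. When no sign change exists the
#' status is `"no_crossing"` and the optimal h is undefined (`NA`); this is
#' a status, not an error.
#'
#' @param result a `sweep_result` with populated curves (the fields
#'   `h_grid`, `epi_curve`, `snr_norm_curve`, `grid_spacing` are used).
#' @return list with `optimal_h`, `crossing_index`, `status`.
#' @export
select_optimal_h <- function(result) {
  hs <- result$h_grid
  d <- result$epi_curve - result$snr_norm_curve
  if (length(d) != length(hs) || length(hs) < 2L)
    stop("sweep curves are not populated", call. = FALSE)
  zero <- which(d == 0)
  if (length(zero) > 0L) {
    i <- zero[1]
    return(list(optimal_h = hs[i], crossing_index = i, status = "crossed"))
  }
  sgn <- which(d[-length(d)] * d[-1] < 0)
  if (length(sgn) == 0L)
    return(list(optimal_h = NA_real_, crossing_index = NA_integer_,
                status = "no_crossing"))
  i <- sgn[1]
  frac <- d[i] / (d[i] - d[i + 1L])
  h_opt <- if (identical(result$grid_spacing, "linear"))
    hs[i] + frac * (hs[i + 1L] - hs[i])
  else
    10^(log10(hs[i]) + frac * (log10(hs[i + 1L]) - log10(hs[i])))
  list(optimal_h = h_opt, crossing_index = i, status = "crossed")
}

#' Denoise the thin-detector image at the selected optimal h
#'
#' Thin delegation to [nlm_denoise()] at `result$optimal_h`; bit-identical
#' to calling the denoiser directly with that smoothing factor.
#'
#' @param thin the thin-detector [raster_image()].
#' @param result a `sweep_result` with `status = "crossed"`.
#' @param nlm_params an [nlm_params()] supplying patch and window radii;
#'   defaults to the parameters stored in the sweep result.
#' @return the denoised [raster_image()].
#' @export
apply_optimal <- function(thin, result, nlm_params = result$nlm) {
  if (!inherits(result, "sweep_result"))
    stop("`result` must be a sweep_result", call. = FALSE)
  if (!identical(result$status, "crossed"))
    stop("no crossing was found: cannot apply an optimal h", call. = FALSE)
  p <- nlm_params
  p$h <- result$optimal_h
  nlm_denoise(thin, p)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d steps on [%.3g, %.3g] (%s), status %s",
              length(x$h_grid), min(x$h_grid), max(x$h_grid),
              x$grid_spacing, x$status))
  if (identical(x$status, "crossed"))
    cat(sprintf(", optimal h = %.4g", x$optimal_h))
  cat("\n")
  invisible(x)
}
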