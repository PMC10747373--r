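#' 2-D normalized noise power spectrum from a flat-field stack
#'
#' For each frame the ensemble-average frame S is subtracted, the difference
#' is tiled into overlapping square ROIs, each ROI is Fourier transformed,
#' and `|F|^2` is averaged over every ROI of every frame. The average
#' periodogram is scaled by `(dx * dy) / (Nx * Ny)` so the spectrum carries
#' standard mm^2 units, and divided by the squared grand mean of S. The DC
#' bin holds residual mean, not noise power, and is excluded from all
#' downstream 1-D averages.
#'
#' @param stack a [flat_field_stack()] (or list of frames accepted by it).
#' @param roi_size ROI side in pixels; a power of two no larger than the
#'   smaller image dimension. Default 128.
#' @param overlap fraction of ROI side shared by adjacent ROIs, in `[0, 1)`.
#'   Default 0.5 (half-overlapping tiles).
#' @return an `nnps_result` with elements `nnps2d` (DC-centered, rows = f_v,
#'   cols = f_u), `f_u`, `f_v` (centered axes, lp/mm), `n_rois`,
#'   `pixel_pitch_mm`, `roi_size`; the 1-D curves are filled by [nnps_1d()].
#' @export
nnps_2d <- function(stack, roi_size = 128L, overlap = 0.5) {
  if (!inherits(stack, "flat_field_stack")) stack <- flat_field_stack(stack)
  nr <- nrow(stack$frames[[1]]$pixels)
  nc <- ncol(stack$frames[[1]]$pixels)
  n <- as.integer(roi_size)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    stop("roi_size must be a power of two", call. = FALSE)
  if (n > min(nr, nc))
    stop("roi_size exceeds the image", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("overlap must be in [0, 1)", call. = FALSE)
  pitch <- stack$pixel_pitch_mm
  if (!is.finite(pitch))
    stop("pixel pitch is required for NNPS (frequency units are lp/mm)",
         call. = FALSE)
  S <- Reduce(`+`, lapply(stack$frames, `[[`, "pixels")) / length(stack$frames)
  mu <- mean(S)
  if (mu == 0) stop("zero grand mean: NNPS undefined", call. = FALSE)
  step <- max(1L, as.integer(round(n * (1 - overlap))))
  r0s <- seq.int(1L, nr - n + 1L, by = step)
  c0s <- seq.int(1L, nc - n + 1L, by = step)
  n_rois <- length(r0s) * length(c0s) * length(stack$frames)
  if (n_rois < 4L)
    stop("fewer than 4 ROIs: NNPS estimate would be unstable", call. = FALSE)
  acc <- matrix(0, n, n)
  for (fr in stack$frames) {
    D <- fr$pixels - S
    for (r0 in r0s) for (c0 in c0s) {
      block <- D[r0:(r0 + n - 1L), c0:(c0 + n - 1L)]
      acc <- acc + Mod(stats::fft(block))^2
    }
  }
  nnps2d <- fftshift2(acc / n_rois) * (pitch * pitch) / (n * n) / mu^2
  structure(list(nnps2d = nnps2d,
                 f_u = fft_freq_centered(n, pitch),
                 f_v = fft_freq_centered(n, pitch),
                 freq_axis_1d = NULL, axial_u = NULL, axial_v = NULL,
                 radial = NULL, n_rois = n_rois,
                 pixel_pitch_mm = pitch, roi_size = n),
            class = "nnps_result")
}

#' 1-D axial and radially averaged NNPS curves
#'
#' The axial curve along `f_u` averages the 2-D NNPS over `band_halfwidth`
#' rows on each side of — and excluding — the `f_v = 0` axis (and
#' symmetrically over the positive and negative frequency half-axes);
#' likewise for `f_v`. The radial curve bins all off-axis cells by radial
#' frequency `sqrt(f_u^2 + f_v^2)` with bin width equal to the frequency
#' sampling interval. All curves run from one frequency step up to Nyquist.
#'
#' @param result an `nnps_result` from [nnps_2d()].
#' @param band_halfwidth rows/columns averaged on each side of the
#'   zero-frequency axis. Default 7 (the customary seven lines flanking the
#'   axis).
#' @return the `nnps_result` with `freq_axis_1d`, `axial_u`, `axial_v` and
#'   `radial` filled in.
#' @export
nnps_1d <- function(result, band_halfwidth = 7L) {
  if (!inherits(result, "nnps_result"))
    stop("`result` must come from nnps_2d()", call. = FALSE)
  n <- result$roi_size
  bw <- as.integer(band_halfwidth)
  i0 <- n %/% 2L + 1L                       # DC index on the shifted grid
  if (bw < 1L || i0 + bw > n)
    stop("band_halfwidth exceeds the frequency grid", call. = FALSE)
  df <- 1 / (n * result$pixel_pitch_mm)
  kmax <- n %/% 2L                          # Nyquist bin
  freq <- seq_len(kmax) * df
  band <- c((i0 - bw):(i0 - 1L), (i0 + 1L):(i0 + bw))
  fold <- function(vals) {
    # vals indexed on the shifted axis; average +k and -k half-axes
    sapply(seq_len(kmax), function(k) {
      idx <- c(if (i0 + k <= n) i0 + k, i0 - k)
      mean(vals[idx])
    })
  }
  m <- result$nnps2d
  result$axial_u <- fold(colMeans(m[band, , drop = FALSE]))
  result$axial_v <- fold(rowMeans(m[, band, drop = FALSE]))
  # radial average, excluding the DC bin and both zero-frequency axes
  fu <- matrix(result$f_u, n, n, byrow = TRUE)
  fv <- matrix(result$f_v, n, n)
  keep <- fu != 0 & fv != 0
  rbin <- as.integer(round(sqrt(fu^2 + fv^2) / df))
  radial <- rep(NA_real_, kmax)
  tab <- tapply(m[keep], rbin[keep], mean)
  ks <- as.integer(names(tab))
  ok <- ks >= 1L & ks <= kmax
  radial[ks[ok]] <- tab[ok]
  result$freq_axis_1d <- freq
  result$radial <- radial
  result
}

#' @export
print.nnps_result <- function(x, ...) {
  cat(sprintf("<nnps_result> %d x %d grid, %d ROIs, pitch %.4g mm%s\n",
              nrow(x$nnps2d), ncol(x$nnps2d), x$n_rois, x$pixel_pitch_mm,
              if (is.null(x$radial)) " (2-D only)" else ""))
  invisible(x)
}
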