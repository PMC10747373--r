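#' Non-local means parameters
#'
#' @param h smoothing factor on the min-max normalized intensity scale
#'   (> 0). Larger values admit less similar patches into the average:
#'   smoother, blurrier output.
#' @param patch_radius half-width of the similarity patch (pixels, >= 0);
#'   the default 1 gives a 3 x 3 patch.
#' @param window_radius half-width of the search window (pixels, >= 1);
#'   the default 2 gives a 5 x 5 window.
#' @return an `nlm_params` object.
#' @export
nlm_params <- function(h = 0.01, patch_radius = 1L, window_radius = 2L) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("`h` must be a single positive number", call. = FALSE)
  if (patch_radius < 0 || patch_radius != round(patch_radius))
    stop("`patch_radius` must be a nonnegative integer", call. = FALSE)
  if (window_radius < 1 || window_radius != round(window_radius))
    stop("`window_radius` must be a positive integer", call. = FALSE)
  structure(list(h = h, patch_radius = as.integer(patch_radius),
                 window_radius = as.integer(window_radius)),
            class = "nlm_params")
}

# Min-max normalization shared by both evaluation paths; constant images
# short-circuit (every patch distance is zero: the convex combination of
# equal values is the identity).
nlm_prepare <- function(img, params) {
  assert_raster(img)
  if (!inherits(params, "nlm_params"))
    stop("`params` must be nlm_params", call. = FALSE)
  lo <- min(img$pixels); hi <- max(img$pixels)
  list(lo = lo, hi = hi, constant = hi == lo,
       norm = if (hi > lo) (img$pixels - lo) / (hi - lo) else img$pixels * 0)
}

#' Non-local means denoising (vectorized evaluation)
#'
#' Each output pixel is a weighted average of the pixels in its search
#' window; the weight of neighbor j at pixel i is
#' `exp(-d(i, j) / (2 h^2)) / Z(i)` where `d(i, j)` is the mean squared
#' difference between the patches centered on i and j and `Z(i)` normalizes
#' the weights to sum to one. The image is min-max normalized to `[0, 1]`
#' before weighting (so `h` is scale-free) and restored to its native scale
#' afterwards. Patches and windows overhanging the border use reflective
#' padding.
#'
#' The accelerated path evaluates one window offset at a time over the whole
#' image, computing all patch distances for that offset with a box filter;
#' it is algebraically identical to [nlm_denoise_reference()], which serves
#' as its brute-force oracle.
#'
#' @param img a [raster_image()].
#' @param params an [nlm_params()].
#' @return a [raster_image()] of the same shape, pitch and native scale.
#' @export
nlm_denoise <- function(img, params) {
  st <- nlm_prepare(img, params)
  if (st$constant) return(img)
  x <- st$norm
  p <- params$patch_radius; w <- params$window_radius
  R <- p + w
  pad <- pad_reflect(x, R)
  nr <- nrow(x); nc <- ncol(x)
  inv2h2 <- 1 / (2 * params$h^2)
  npatch <- (2 * p + 1)^2
  num <- matrix(0, nr, nc)
  den <- matrix(0, nr, nc)
  for (dr in -w:w) {
    for (dc in -w:w) {
      # squared difference field on the patch-padded frame of the image:
      # rows (R - p + dr') for dr' in ... ; index so that entry (u, v) of
      # `sq` is (pad[u + w, v + w] - pad[u + w + dr, v + w + dc])^2, giving
      # a (nr + 2p) x (nc + 2p) grid centered on the image.
      ui <- (w + 1L):(w + nr + 2L * p)
      vi <- (w + 1L):(w + nc + 2L * p)
      sq <- (pad[ui, vi, drop = FALSE] -
             pad[ui + dr, vi + dc, drop = FALSE])^2
      d <- box_sum(sq, p) / npatch
      wt <- exp(-d * inv2h2)
      nb <- pad[(R + 1L + dr):(R + nr + dr), (R + 1L + dc):(R + nc + dc),
                drop = FALSE]
      num <- num + wt * nb
      den <- den + wt
    }
  }
  out <- num / den
  raster_image(out * (st$hi - st$lo) + st$lo, img$pixel_pitch_mm,
               value_range = img$value_range)
}

#' Non-local means denoising (brute-force reference path)
#'
#' Naive double-loop evaluation of the same weighted average as
#' [nlm_denoise()]; O(N * W^2 * P^2) time. It exists as the independent
#' oracle for the accelerated path and asserts the weight-normalization
#' invariant (weights sum to 1) at every pixel.
#'
#' @inheritParams nlm_denoise
#' @return a [raster_image()].
#' @export
nlm_denoise_reference <- function(img, params) {
  st <- nlm_prepare(img, params)
  if (st$constant) return(img)
  x <- st$norm
  p <- params$patch_radius; w <- params$window_radius
  R <- p + w
  pad <- pad_reflect(x, R)
  nr <- nrow(x); nc <- ncol(x)
  inv2h2 <- 1 / (2 * params$h^2)
  npatch <- (2 * p + 1)^2
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rc <- r + R; cc <- c + R            # centre in padded coords
      pi_ <- pad[(rc - p):(rc + p), (cc - p):(cc + p)]
      wts <- numeric((2 * w + 1)^2)
      vals <- numeric((2 * w + 1)^2)
      k <- 0L
      for (dr in -w:w) {
        for (dc in -w:w) {
          k <- k + 1L
          pj <- pad[(rc + dr - p):(rc + dr + p), (cc + dc - p):(cc + dc + p)]
          d <- mean((pi_ - pj)^2)
          wts[k] <- exp(-d * inv2h2)
          vals[k] <- pad[rc + dr, cc + dc]
        }
      }
      wts <- wts / sum(wts)
      stopifnot(abs(sum(wts) - 1) < 1e-12)   # Z(i) normalization invariant
      out[r, c] <- sum(wts * vals)
    }
  }
  raster_image(out * (st$hi - st$lo) + st$lo, img$pixel_pitch_mm,
               value_range = img$value_range)
}
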