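# Per-row edge localisation shared by angle estimation and ESF projection.
# Returns 0-based (row_center, col_position) pairs for rows with a usable
# transition: the position is the centroid of the absolute row derivative,
# taken within a window around the derivative peak so that noise far from
# the edge cannot drag the centroid toward the row centre. Rows whose
# derivative peak does not rise above 5x the row's MAD are dropped as
# transition-free.
edge_row_positions <- function(block, centroid_halfwidth = 8L) {
  nr <- nrow(block)
  rows <- numeric(0); pos <- numeric(0)
  for (r in seq_len(nr)) {
    d <- diff(block[r, ])
    ad <- abs(d)
    m <- max(ad)
    if (!(m > 5 * stats::mad(d)) || m == 0) next
    pk <- which.max(ad)
    win <- max(1L, pk - centroid_halfwidth):min(length(ad), pk + centroid_halfwidth)
    # derivative sample j sits on the border between columns j-1 and j
    # (0-based continuous coordinate j within the block)
    rows <- c(rows, r - 0.5)
    pos <- c(pos, sum(ad[win] * win) / sum(ad[win]))
  }
  list(rows = rows, pos = pos)
}

edge_fit <- function(img, roi) {
  block <- roi_extract(img, roi)
  ep <- edge_row_positions(block)
  if (length(ep$rows) < 10L)
    stop("fewer than 10 rows with a detectable edge transition in ROI",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, ep$rows), ep$pos)
  list(intercept = unname(fit$coefficients[1]),
       slope = unname(fit$coefficients[2]),
       n_rows = length(ep$rows))
}

#' Estimate the tilt of a near-vertical edge
#'
#' Locates the edge in every ROI row as the centroid of the absolute row
#' derivative, then fits a least-squares line through the (row, position)
#' pairs. Rows without a detectable transition (derivative peak below five
#' times the row's median absolute deviation) are dropped; fewer than 10
#' usable rows is an error.
#'
#' @param img a [raster_image()].
#' @param roi a [rect_roi()] spanning the edge; the edge must be roughly
#'   vertical (within about 10 degrees).
#' @return tilt from vertical in degrees (signed).
#' @export
estimate_edge_angle <- function(img, roi) {
  atan(edge_fit(img, roi)$slope) * 180 / pi
}

#' Presampled MTF by the slanted-edge method
#'
#' Projects the ROI pixels onto the edge normal using the estimated tilt,
#' bins the projections into an oversampled edge-spread function (bin width
#' `pitch / oversample`), differentiates by central differences to the
#' line-spread function, applies a Hann window centered on the LSF peak,
#' and takes the Fourier magnitude normalized at DC. The transfer functions
#' of the finite-difference derivative and of the projection bin aperture
#' are divided out so a noiseless pixel-aperture edge reproduces its
#' analytic sinc MTF. The curve is reported up to the presampled Nyquist
#' frequency `1 / (2 * pitch)`; the 10%-MTF frequency is found by linear
#' interpolation, or reported as Nyquist with `f10_at_nyquist = TRUE` when
#' the curve never falls below 0.10.
#'
#' @param img a [raster_image()] containing a tilted edge.
#' @param roi a [rect_roi()] spanning the edge.
#' @param oversample sub-pixel binning factor, 4 (default) or 8.
#' @return an `mtf_result`: `freq` (lp/mm), `mtf`, `f10`, `f10_at_nyquist`,
#'   `edge_angle_deg`, `esf_oversample`, `esf`, `esf_position_mm`.
#' @export
compute_mtf <- function(img, roi, oversample = 4L) {
  assert_raster(img)
  if (!oversample %in% c(4L, 8L))
    stop("oversample must be 4 or 8", call. = FALSE)
  pitch <- img$pixel_pitch_mm
  if (!is.finite(pitch))
    stop("pixel pitch is required for MTF (frequency units are lp/mm)",
         call. = FALSE)
  fit <- edge_fit(img, roi)
  theta <- atan(fit$slope)
  block <- roi_extract(img, roi)
  nr <- nrow(block); nc <- ncol(block)
  # signed distance (pixels) from the fitted edge line, along its normal
  rr <- matrix(seq_len(nr) - 0.5, nr, nc)
  cc <- matrix(seq_len(nc) - 0.5, nr, nc, byrow = TRUE)
  t_px <- (cc - (fit$intercept + fit$slope * rr)) * cos(theta)
  db <- pitch / oversample
  t_mm <- t_px * pitch
  bin <- floor(t_mm / db)
  bin <- bin - min(bin)
  nb <- max(bin) + 1L
  esf <- rep(NA_real_, nb)
  cnt <- tabulate(bin + 1L, nbins = nb)
  agg <- tapply(as.vector(block), as.vector(bin), mean)
  esf[as.integer(names(agg)) + 1L] <- agg
  n_empty <- sum(cnt == 0L)
  if (n_empty > 0.1 * nb)
    stop(sprintf("%d of %d ESF bins are empty (> 10%%): tilt too small or ROI too short",
                 n_empty, nb), call. = FALSE)
  if (n_empty > 0L) {
    idx <- which(!is.na(esf))
    esf <- stats::approx(idx, esf[idx], xout = seq_len(nb), rule = 2)$y
  }
  # central-difference LSF (interior bins only)
  lsf <- (esf[3:nb] - esf[1:(nb - 2L)]) / 2
  nl <- length(lsf)
  pk <- which.max(abs(lsf))
  hw <- max(min(pk - 1L, nl - pk), 4L)
  i <- seq_len(nl)
  win <- ifelse(abs(i - pk) <= hw, 0.5 * (1 + cos(pi * (i - pk) / hw)), 0)
  lw <- lsf * win
  spec <- Mod(stats::fft(lw))
  if (spec[1] == 0) stop("degenerate LSF: zero DC response", call. = FALSE)
  freq_all <- (seq_len(nl) - 1L) / (nl * db)
  nyq <- 1 / (2 * pitch)
  keep <- freq_all <= nyq + 1e-12
  freq <- freq_all[keep]
  mtf <- spec[keep] / spec[1]
  # divide out finite-difference derivative and bin-aperture responses
  corr <- sinc_pi(2 * pi * freq * db) * sinc_pi(pi * freq * db)
  mtf <- pmax(mtf / corr, 0)
  mtf[1] <- 1
  below <- which(mtf < 0.10)
  if (length(below) == 0L) {
    f10 <- nyq; at_nyq <- TRUE
  } else {
    j <- below[1]
    f10 <- freq[j - 1L] + (freq[j] - freq[j - 1L]) *
      (mtf[j - 1L] - 0.10) / (mtf[j - 1L] - mtf[j])
    at_nyq <- FALSE
  }
  structure(list(freq = freq, mtf = mtf, f10 = f10, f10_at_nyquist = at_nyq,
                 edge_angle_deg = theta * 180 / pi,
                 esf_oversample = as.integer(oversample),
                 esf = esf, esf_position_mm = (seq_len(nb) - 0.5) * db,
                 pixel_pitch_mm = pitch),
            class = "mtf_result")
}

#' @export
print.mtf_result <- function(x, ...) {
  cat(sprintf("<mtf_result> %d frequencies to %.3g lp/mm, f10 = %.3g lp/mm%s, angle %.2f deg\n",
              length(x$freq), max(x$freq), x$f10,
              if (x$f10_at_nyquist) " (at Nyquist)" else "",
              x$edge_angle_deg))
  invisible(x)
}
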