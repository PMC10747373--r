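#' Edge preservation index
#'
#' Correlation of Laplacian-filtered reference and measured images over a
#' region of interest: both images are filtered with the discrete
#' four-neighbor Laplacian (reflective boundaries, applied to the full image
#' before restriction to the ROI so the ROI border carries no filtering
#' artifacts), mean-subtracted over the ROI, and correlated:
#' `Gamma(a, b) / sqrt(Gamma(a, a) * Gamma(b, b))` with
#' `Gamma(a, b) = sum_ROI a * b`. A value of 1 means the measured image
#' preserves the reference's edge structure exactly; the index is symmetric
#' in its two images and invariant to positive affine rescaling of either.
#'
#' @param reference,measured same-shape [raster_image()]s (or matrices).
#' @param roi a [rect_roi()] valid for both images; the Laplacian response
#'   must be non-constant inside it for both images.
#' @return a scalar in `[-1, 1]`.
#' @export
epi <- function(reference, measured, roi) {
  ref <- if (is_raster_image(reference)) reference$pixels else reference
  mea <- if (is_raster_image(measured)) measured$pixels else measured
  if (!identical(dim(ref), dim(mea)))
    stop("reference and measured images must have the same shape", call. = FALSE)
  check_roi(roi, ref)
  a <- roi_extract(laplacian4(ref), roi)
  b <- roi_extract(laplacian4(mea), roi)
  a <- a - mean(a)
  b <- b - mean(b)
  ga <- sum(a * a); gb <- sum(b * b)
  if (ga == 0 || gb == 0)
    stop("zero Laplacian variance in ROI: edge preservation index undefined",
         call. = FALSE)
  sum(a * b) / sqrt(ga * gb)
}

#' ROI signal-to-noise ratio
#'
#' Mean divided by the population standard deviation (divisor N) of the
#' pixels in a nominally uniform region.
#'
#' @param img a [raster_image()] or numeric matrix.
#' @param roi a [rect_roi()].
#' @return a nonnegative scalar.
#' @export
roi_snr <- function(img, roi) {
  v <- as.vector(roi_extract(img, roi))
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0)
    stop("homogeneous ROI: standard deviation is zero, SNR undefined",
         call. = FALSE)
  mean(v) / s
}

# Registry for pluggable no-reference quality backends.
.nr_backends <- new.env(parent = emptyenv())

#' Register a no-reference image-quality backend
#'
#' @param name backend name.
#' @param fun function taking a numeric matrix and returning a scalar score
#'   (lower = more natural), or `NULL` to unregister.
#' @return previous backend, invisibly.
#' @export
register_nr_backend <- function(name, fun) {
  old <- .nr_backends[[name]]
  if (is.null(fun)) {
    if (!is.null(old)) rm(list = name, envir = .nr_backends)
  } else {
    stopifnot(is.function(fun))
    .nr_backends[[name]] <- fun
  }
  invisible(old)
}

#' No-reference image-quality score (BRISQUE-style adapter)
#'
#' Delegates to a registered external backend (see
#' [register_nr_backend()]) and returns its scalar unchanged; the score's
#' internals are deliberately out of scope here. When no backend is
#' registered a capability error (condition class
#' `scintopt_missing_backend`) is raised naming the optional hook.
#'
#' @param img a [raster_image()] of at least 64 x 64 pixels.
#' @param backend backend name; default `"brisque"`.
#' @return scalar score (lower = more natural).
#' @export
no_reference_score <- function(img, backend = "brisque") {
  assert_raster(img)
  if (nrow(img$pixels) < 64L || ncol(img$pixels) < 64L)
    stop("no-reference scoring needs an image of at least 64 x 64 pixels",
         call. = FALSE)
  fun <- .nr_backends[[backend]]
  if (is.null(fun))
    stop(structure(class = c("scintopt_missing_backend", "error", "condition"),
                   list(message = sprintf(
                     paste0("no '%s' backend registered: install an external ",
                            "no-reference scorer and register it with ",
                            "register_nr_backend()"), backend),
                        call = NULL)))
  as.numeric(fun(img$pixels))
}
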