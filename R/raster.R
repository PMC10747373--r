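#' 2-D grayscale raster image with physical pixel pitch
#'
#' The universal currency of every stage of the pipeline: a numeric matrix of
#' intensities together with the sampling pitch in millimetres and the native
#' value range of the acquisition chain.
#'
#' @param pixels numeric matrix (rows x cols) of finite intensities.
#' @param pixel_pitch_mm sampling pitch in mm (> 0), or `NA` when unknown;
#'   stages that work in physical units reject an image without a pitch.
#' @param value_range length-2 numeric `(min, max)` of the native scale, e.g.
#'   `c(0, 65535)` for a 16-bit detector. Defaults to the range of `pixels`.
#' @return an object of class `raster_image`.
#' @export
raster_image <- function(pixels, pixel_pitch_mm, value_range = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image contains non-finite pixel values", call. = FALSE)
  if (!is.numeric(pixel_pitch_mm) || length(pixel_pitch_mm) != 1L ||
      (!is.na(pixel_pitch_mm) && (!is.finite(pixel_pitch_mm) || pixel_pitch_mm <= 0)))
    stop("`pixel_pitch_mm` must be a single positive number or NA", call. = FALSE)
  storage.mode(pixels) <- "double"
  if (is.null(value_range)) value_range <- range(pixels)
  if (length(value_range) != 2L || !all(is.finite(value_range)) ||
      value_range[2] < value_range[1])
    stop("`value_range` must be a finite (min, max) pair", call. = FALSE)
  structure(
    list(pixels = unname(pixels),
         pixel_pitch_mm = as.numeric(pixel_pitch_mm),
         value_range = as.numeric(value_range)),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px, pitch %.4g mm, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_pitch_mm,
              x$value_range[1], x$value_range[2]))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

#' @rdname raster_image
#' @param x object to test or coerce.
#' @export
is_raster_image <- function(x) inherits(x, "raster_image")

assert_raster <- function(x, arg = deparse(substitute(x))) {
  if (!is_raster_image(x))
    stop(sprintf("`%s` must be a raster_image", arg), call. = FALSE)
  invisible(x)
}

#' Rectangular region of interest
#'
#' ROIs use the package-wide coordinate convention: 0-based, row-major,
#' half-open (rows `[row0, row0 + height)`, columns `[col0, col0 + width)`).
#'
#' @param row0,col0 top-left corner, 0-based pixel indices.
#' @param height,width extent in pixels; `height * width >= 4`.
#' @return an object of class `rect_roi`.
#' @export
rect_roi <- function(row0, col0, height, width) {
  v <- c(row0 = row0, col0 = col0, height = height, width = width)
  if (!all(is.finite(v)) || any(v != round(v)))
    stop("ROI fields must be integers", call. = FALSE)
  if (row0 < 0 || col0 < 0 || height < 1 || width < 1)
    stop("ROI must have non-negative origin and positive extent", call. = FALSE)
  if (height * width < 4)
    stop("ROI must cover at least 4 pixels", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "rect_roi")
}

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("<rect_roi> rows [%d, %d), cols [%d, %d)\n",
              x$row0, x$row0 + x$height, x$col0, x$col0 + x$width))
  invisible(x)
}

# Shared ROI-containment validation (io_cli coordinate contract).
check_roi <- function(roi, img, arg = "roi") {
  if (!inherits(roi, "rect_roi"))
    stop(sprintf("`%s` must be a rect_roi", arg), call. = FALSE)
  px <- if (is_raster_image(img)) img$pixels else img
  if (roi$row0 + roi$height > nrow(px) || roi$col0 + roi$width > ncol(px))
    stop(sprintf("`%s` (rows [%d,%d), cols [%d,%d)) is not contained in the %d x %d image",
                 arg, roi$row0, roi$row0 + roi$height, roi$col0,
                 roi$col0 + roi$width, nrow(px), ncol(px)), call. = FALSE)
  invisible(roi)
}

#' Extract the pixel block covered by an ROI
#'
#' @param img a `raster_image` or numeric matrix.
#' @param roi a [rect_roi()].
#' @return numeric matrix of the ROI pixels.
#' @export
roi_extract <- function(img, roi) {
  check_roi(roi, img)
  px <- if (is_raster_image(img)) img$pixels else img
  px[(roi$row0 + 1L):(roi$row0 + roi$height),
     (roi$col0 + 1L):(roi$col0 + roi$width), drop = FALSE]
}
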