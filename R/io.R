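#' Read a grayscale image (or multi-page stack) from disk
#'
#' Accepts single- or multi-page grayscale TIFF (the primary format; raw
#' integer counts are returned unrescaled), grayscale PNG (fallback; sample
#' values are returned on the 16-bit scale), or headerless raw with explicit
#' shape and dtype. The pixel pitch is attached from the `pitch_mm` argument
#' or, failing that, from a JSON sidecar `<path>.json` with a
#' `pixel_pitch_mm` field; the argument wins. A missing pitch is not an
#' error on read — stages working in physical units reject it later.
#'
#' @param path file path (`.tif`/`.tiff`, `.png`, or raw).
#' @param pitch_mm pixel pitch in mm (optional).
#' @param shape `c(rows, cols)`, required for headerless raw input.
#' @param dtype raw-input sample type: `"uint16"`, `"uint8"` or `"float32"`.
#' @return a [raster_image()], or a [flat_field_stack()] for multi-page TIFF.
#' @export
read_image <- function(path, pitch_mm = NULL, shape = NULL,
                       dtype = c("uint16", "uint8", "float32")) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  pitch <- pitch_mm
  if (is.null(pitch)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (!is.null(meta$pixel_pitch_mm)) pitch <- as.numeric(meta$pixel_pitch_mm)
    }
  }
  if (is.null(pitch)) pitch <- NA_real_
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    pages <- lapply(pages, reject_rgb, path = path)
    if (length(pages) == 1L)
      return(raster_image(pages[[1]], pitch))
    return(flat_field_stack(lapply(pages, raster_image,
                                   pixel_pitch_mm = pitch)))
  }
  if (ext == "png") {
    px <- png::readPNG(path)
    px <- reject_rgb(px, path)
    # readPNG rescales samples to [0, 1]; restore the 16-bit count scale
    return(raster_image(round(px * 65535), pitch, value_range = c(0, 65535)))
  }
  dtype <- match.arg(dtype)
  if (is.null(shape) || length(shape) != 2L)
    stop("headerless raw input needs shape = c(rows, cols)", call. = FALSE)
  n <- prod(shape)
  v <- switch(dtype,
    uint16 = readBin(path, "integer", n, size = 2L, signed = FALSE,
                     endian = "little"),
    uint8 = as.integer(readBin(path, "raw", n)),
    float32 = readBin(path, "double", n, size = 4L, endian = "little"))
  if (length(v) != n) stop("raw file shorter than the requested shape", call. = FALSE)
  raster_image(matrix(v, shape[1], shape[2], byrow = TRUE), pitch)
}

reject_rgb <- function(px, path) {
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] == 1L) return(px[, , 1])
    stop(sprintf(paste0("%s is not grayscale (%d channels): convert it to a ",
                        "single-channel image first"), path, dim(px)[3]),
         call. = FALSE)
  }
  px
}

#' Write an image or flat-field stack as 16-bit grayscale TIFF
#'
#' Values are rounded, clipped to the sample range and written at the
#' requested bit depth; stacks become multi-page TIFFs. A JSON sidecar
#' `<path>.json` records the pixel pitch so [read_image()] can restore it.
#'
#' @param img a [raster_image()] or [flat_field_stack()].
#' @param path output path.
#' @param bits_per_sample 8 or 16 (default).
#' @param sidecar write the pitch sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits_per_sample = 16L, sidecar = TRUE) {
  vmax <- 2^bits_per_sample - 1
  enc <- function(m) pmin(pmax(round(m), 0), vmax) / vmax
  if (inherits(img, "flat_field_stack")) {
    tiff::writeTIFF(lapply(img$frames, function(f) enc(f$pixels)), path,
                    bits.per.sample = bits_per_sample)
    pitch <- img$pixel_pitch_mm
  } else {
    assert_raster(img)
    tiff::writeTIFF(enc(img$pixels), path, bits.per.sample = bits_per_sample)
    pitch <- img$pixel_pitch_mm
  }
  if (sidecar && is.finite(pitch))
    write_sidecar(paste0(path, ".json"), list(pixel_pitch_mm = pitch))
  invisible(path)
}

# 17 significant digits: enough for an exact double round trip through text.
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_curve_csv <- function(df, path) {
  txt <- vapply(df, format_num, character(nrow(df)))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = 1L)
  colnames(txt) <- names(df)
  utils::write.table(txt, path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a JSON parameter sidecar
#'
#' Every pipeline run records its effective parameters and the package
#' version next to its outputs, so a run can be reproduced from its sidecar
#' alone.
#'
#' @param path output path.
#' @param params named list of parameters.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(path, params) {
  params$package <- "scintopt"
  params$version <- as.character(utils::packageVersion("scintopt"))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write pipeline results to CSV (curves) and JSON (scalars/settings)
#'
#' Curves are written as UTF-8 CSV with a header row, `.` decimal separator
#' and 17 significant digits, so re-reading reproduces them exactly; scalar
#' results and settings go to a JSON sidecar `<path>.json`.
#'
#' @param result a `sweep_result`, `nnps_result` or `mtf_result`.
#' @param path output CSV path.
#' @param extra named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, extra = list()) {
  UseMethod("write_results")
}

#' @export
write_results.sweep_result <- function(result, path, extra = list()) {
  write_curve_csv(data.frame(h = result$h_grid, epi = result$epi_curve,
                             snr_norm = result$snr_norm_curve), path)
  write_sidecar(paste0(path, ".json"), c(list(
    kind = "sweep", status = result$status, optimal_h = result$optimal_h,
    crossing_index = result$crossing_index,
    grid_spacing = result$grid_spacing,
    h_min = min(result$h_grid), h_max = max(result$h_grid),
    n_steps = length(result$h_grid),
    epi_roi = unclass(result$epi_roi), snr_roi = unclass(result$snr_roi),
    patch_radius = result$nlm$patch_radius,
    window_radius = result$nlm$window_radius), extra))
  invisible(path)
}

#' @export
write_results.nnps_result <- function(result, path, extra = list()) {
  if (is.null(result$freq_axis_1d))
    stop("run nnps_1d() before writing NNPS results", call. = FALSE)
  write_curve_csv(data.frame(frequency = result$freq_axis_1d,
                             axial_u = result$axial_u,
                             axial_v = result$axial_v,
                             radial = result$radial), path)
  write_sidecar(paste0(path, ".json"), c(list(
    kind = "nnps", n_rois = result$n_rois, roi_size = result$roi_size,
    pixel_pitch_mm = result$pixel_pitch_mm), extra))
  invisible(path)
}

#' @export
write_results.mtf_result <- function(result, path, extra = list()) {
  write_curve_csv(data.frame(frequency = result$freq, mtf = result$mtf), path)
  write_sidecar(paste0(path, ".json"), c(list(
    kind = "mtf", f10 = result$f10, f10_at_nyquist = result$f10_at_nyquist,
    edge_angle_deg = result$edge_angle_deg,
    esf_oversample = result$esf_oversample,
    pixel_pitch_mm = result$pixel_pitch_mm), extra))
  invisible(path)
}

#' Read a curve CSV written by [write_results()]
#'
#' @param path CSV path.
#' @return a data.frame of numeric columns.
#' @export
read_curves_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
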