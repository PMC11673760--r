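#' Greyscale image frame with bit depth and spatial calibration
#'
#' The unit all pipeline stages consume and produce: a 2-D matrix of
#' non-negative integer intensities together with its bit depth (8 or 16)
#' and, for optical images, a spatial calibration in micrometres per pixel.
#'
#' @param pixels numeric matrix of intensities, row = image row.
#' @param bit_depth integer, 8 or 16.
#' @param pixel_size_um micrometres per pixel (NA if uncalibrated).
#' @return an object of class \code{image_frame}.
#' @export
image_frame <- function(pixels, bit_depth = 16L, pixel_size_um = NA_real_) {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxval))
    stop("pixel values outside [0, ", maxval, "]")
  if (!is.na(pixel_size_um) && pixel_size_um <= 0)
    stop("pixel_size_um must be positive")
  structure(
    list(pixels = pixels, bit_depth = bit_depth, pixel_size_um = pixel_size_um),
    class = "image_frame"
  )
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf(
    "<image_frame> %d x %d px, %d-bit, pixel size %s um/px, range [%g, %g]\n",
    nrow(x$pixels), ncol(x$pixels), x$bit_depth,
    ifelse(is.na(x$pixel_size_um), "uncalibrated", format(x$pixel_size_um)),
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.image_frame <- function(x) dim(x$pixels)

max_intensity <- function(frame) 2^frame$bit_depth - 1

stopifnot_frame <- function(frame) {
  if (!inherits(frame, "image_frame")) stop("expected an 'image_frame' object")
  invisible(frame)
}

#' Convert a frame to 8-bit
#'
#' 16-bit frames are mapped linearly from their own [min, max] onto
#' [0, 255] with round-half-away-from-zero, mirroring the display-range
#' scaling conventionally applied before greyscale analysis. 8-bit input
#' is returned unchanged. A constant 16-bit frame has no range to scale
#' and maps to all zeros with a warning. Calibration is preserved.
#'
#' @param frame an \code{image_frame}.
#' @return an 8-bit \code{image_frame}.
#' @export
convert_to_8bit <- function(frame) {
  stopifnot_frame(frame)
  if (frame$bit_depth == 8L) return(frame)
  px <- frame$pixels
  lo <- min(px); hi <- max(px)
  if (hi == lo) {
    warning("constant 16-bit frame: mapping to all zeros")
    out <- matrix(0, nrow(px), ncol(px))
  } else {
    out <- floor((px - lo) / (hi - lo) * 255 + 0.5)
  }
  image_frame(out, 8L, frame$pixel_size_um)
}

#' Read a greyscale TIFF into an image frame
#'
#' Calibration is attached from the caller, never from TIFF tags; any
#' resolution tags present are ignored (the two microscopes involved are
#' handled purely through the per-run pixel-size setting).
#'
#' @param path TIFF file path.
#' @param pixel_size_um spatial calibration to attach.
#' @return an \code{image_frame} with bit depth detected from the file.
#' @export
read_image <- function(path, pixel_size_um = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  px <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                 error = function(e) stop("cannot read TIFF '", path, "': ",
                                          conditionMessage(e)))
  if (length(dim(px)) != 2L)
    stop("'", path, "' is not single-channel greyscale")
  bits <- attr(px, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(px) > 255) 16L else 8L
  if (!bits %in% c(8L, 16L))
    stop("'", path, "' has unsupported bit depth ", bits)
  image_frame(matrix(as.numeric(px), nrow(px), ncol(px)), as.integer(bits),
              pixel_size_um)
}

#' Write an image frame as greyscale TIFF
#'
#' @param frame an \code{image_frame}.
#' @param path output file path.
#' @export
write_image <- function(frame, path) {
  stopifnot_frame(frame)
  tiff::writeTIFF(frame$pixels / max_intensity(frame), path,
                  bits.per.sample = frame$bit_depth)
  invisible(path)
}
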