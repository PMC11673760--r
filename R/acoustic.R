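#' Well region of interest on a B-mode frame
#'
#' Wells bored in the phantom have a known physical diameter (8 mm); the
#' ROI spans that width in pixels via the frame's pixel pitch. B-mode
#' echoes from a well form a band, so the default ROI is rectangular with
#' an explicit height; a circular option matches the well plan view.
#'
#' @param center_px c(row, col) of the ROI centre.
#' @param pixel_pitch_mm millimetres per pixel of the frame.
#' @param diameter_mm physical well diameter.
#' @param height_px ROI height in pixels (rectangular shape only);
#'   defaults to the diameter in pixels.
#' @param shape "rect" or "circle".
#' @return a \code{well_roi} object.
#' @export
well_roi <- function(center_px, pixel_pitch_mm, diameter_mm = 8,
                     height_px = NULL, shape = c("rect", "circle")) {
  shape <- match.arg(shape)
  if (diameter_mm <= 0 || pixel_pitch_mm <= 0)
    stop("diameter and pixel pitch must be positive")
  width_px <- diameter_mm / pixel_pitch_mm
  if (is.null(height_px)) height_px <- width_px
  structure(list(center_px = as.numeric(center_px),
                 pixel_pitch_mm = pixel_pitch_mm,
                 diameter_mm = diameter_mm,
                 width_px = width_px, height_px = height_px, shape = shape),
            class = "well_roi")
}

roi_indices <- function(frame, roi) {
  nr <- nrow(frame$pixels); nc <- ncol(frame$pixels)
  if (roi$shape == "rect") {
    r0 <- ceiling(roi$center_px[1] - roi$height_px / 2)
    r1 <- floor(roi$center_px[1] + roi$height_px / 2)
    c0 <- ceiling(roi$center_px[2] - roi$width_px / 2)
    c1 <- floor(roi$center_px[2] + roi$width_px / 2)
    if (r0 < 1 || c0 < 1 || r1 > nr || c1 > nc)
      stop("ROI extends outside the frame")
    list(rows = r0:r1, cols = c0:c1, mask = NULL)
  } else {
    rad <- roi$width_px / 2
    if (roi$center_px[1] - rad < 1 || roi$center_px[1] + rad > nr ||
        roi$center_px[2] - rad < 1 || roi$center_px[2] + rad > nc)
      stop("ROI extends outside the frame")
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    list(rows = NULL, cols = NULL,
         mask = (rows - roi$center_px[1])^2 +
           (cols - roi$center_px[2])^2 <= rad^2)
  }
}

#' Mean greyscale intensity inside a well ROI
#'
#' @param frame8 an 8-bit \code{image_frame}.
#' @param roi a \code{well_roi}.
#' @return arithmetic mean of the pixels inside the ROI.
#' @export
mean_roi_intensity <- function(frame8, roi) {
  stopifnot_frame(frame8)
  if (!inherits(roi, "well_roi")) stop("expected a well_roi")
  ix <- roi_indices(frame8, roi)
  if (is.null(ix$mask)) mean(frame8$pixels[ix$rows, ix$cols])
  else mean(frame8$pixels[ix$mask])
}

#' Subtract the mean background frame from post-injection frames
#'
#' The pixelwise mean of the pre-injection (background) frames is
#' subtracted from every post-injection frame to remove stationary
#' transducer artifacts; results are clipped at 0 (the unclipped frames
#' are attached as attribute \code{unclipped} for diagnostics, since
#' clipping biases pure-noise wells positively).
#'
#' @param after_frames list of \code{image_frame}s post injection.
#' @param background_frames list of \code{image_frame}s pre injection.
#' @return list of corrected \code{image_frame}s.
#' @export
subtract_mean_background <- function(after_frames, background_frames) {
  if (length(background_frames) < 1L) stop("need at least one background frame")
  dims <- lapply(c(after_frames, background_frames), function(f) dim(f$pixels))
  if (length(unique(dims)) != 1L) stop("frame geometry mismatch")
  bg <- Reduce(`+`, lapply(background_frames, `[[`, "pixels")) /
    length(background_frames)
  out <- lapply(after_frames, function(f) {
    raw <- f$pixels - bg
    g <- image_frame(pmax(raw, 0), f$bit_depth, f$pixel_size_um)
    attr(g, "unclipped") <- raw
    g
  })
  out
}

#' Decibel change in mean intensity
#'
#' I_dB = 10 * log10(I_after / I_before): positive when the well brightened
#' after contrast injection. Vectorized.
#'
#' @param I_after mean greyscale after injection (>= 0).
#' @param I_before mean greyscale before injection (> 0).
#' @return dB change; \code{-Inf} (with a warning) where I_after is 0.
#' @export
decibel_change <- function(I_after, I_before) {
  if (any(I_before <= 0)) stop("I_before must be positive: dB undefined")
  if (any(I_after < 0)) stop("I_after must be non-negative")
  if (any(I_after == 0))
    warning("I_after of 0 yields -Inf dB")
  10 * log10(I_after / I_before)
}

#' Measure a panel of wells before and after injection
#'
#' For each ROI: mean intensity over the background frames (I_before), over
#' the post-injection frames (I_after), over the background-subtracted
#' post-injection frames (I_after_bg_subtracted), and the per-well dB
#' change 10*log10(I_after/I_before).
#'
#' 16-bit frames are brought to the 8-bit display scale with the fixed
#' full-range factor 255/65535 (not per-frame min-max): the decibel change
#' is a ratio of before/after intensities, and a per-frame contrast stretch
#' would make that ratio depend on each frame's brightest and darkest
#' speckle rather than on the echo intensity.
#'
#' @param before_frames list of \code{image_frame}s pre injection.
#' @param after_frames list of \code{image_frame}s post injection.
#' @param rois list of \code{well_roi}s.
#' @return data frame of class \code{well_measurements}, one row per well.
#' @export
measure_well_panel <- function(before_frames, after_frames, rois) {
  to8 <- function(fl) lapply(fl, function(f) {
    if (f$bit_depth == 8L) f
    else image_frame(f$pixels * (255 / 65535), 8L, f$pixel_size_um)
  })
  before8 <- to8(before_frames); after8 <- to8(after_frames)
  corrected <- subtract_mean_background(after8, before8)
  rows <- lapply(seq_along(rois), function(k) {
    roi <- rois[[k]]
    ib <- mean(vapply(before8, mean_roi_intensity, numeric(1), roi = roi))
    ia <- mean(vapply(after8, mean_roi_intensity, numeric(1), roi = roi))
    ic <- mean(vapply(corrected, mean_roi_intensity, numeric(1), roi = roi))
    data.frame(well = k, I_before = ib, I_after = ia,
               I_after_bg_subtracted = ic,
               delta_dB = decibel_change(ia, ib))
  })
  structure(do.call(rbind, rows),
            class = c("well_measurements", "data.frame"))
}

#' Summarize a panel of well measurements
#'
#' Mean and SD of the post-injection intensity across replicate wells, and
#' the panel dB change computed from the panel-mean intensities (not the
#' mean of per-well dBs).
#'
#' @param measurements a \code{well_measurements} data frame.
#' @return object of class \code{well_panel}: n_wells, mean/SD of I_after,
#'   mean I_before, mean_delta_dB.
#' @export
summarize_wells <- function(measurements) {
  if (nrow(measurements) < 1L) stop("need at least one well")
  n <- nrow(measurements)
  sd_after <- if (n > 1) stats::sd(measurements$I_after) else {
    warning("single well: SD is 0 by convention")
    0
  }
  structure(list(n_wells = n,
                 mean_I_before = mean(measurements$I_before),
                 mean_I_after = mean(measurements$I_after),
                 sd_I_after = sd_after,
                 mean_delta_dB = decibel_change(mean(measurements$I_after),
                                                mean(measurements$I_before))),
            class = "well_panel")
}

#' @export
print.well_panel <- function(x, ...) {
  cat(sprintf(
    "Well panel (n = %d): I_after %.2f +/- %.2f (I_before %.2f), dB change %+.3f\n",
    x$n_wells, x$mean_I_after, x$sd_I_after, x$mean_I_before, x$mean_delta_dB))
  invisible(x)
}
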