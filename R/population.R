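#' Equivalent diameter from equivalent radius
#'
#' The optical chain reports equivalent-circle radii; size standards are
#' specified by diameter, so reported radii are multiplied by two for
#' comparison (1 um beads have 0.5 um radius, 3 um beads 1.5 um).
#'
#' @param radius_um equivalent radius, um (vectorized).
#' @return diameter in um.
#' @export
equiv_diameter <- function(radius_um) {
  if (any(radius_um <= 0)) stop("radius must be positive")
  2 * radius_um
}

#' Square-root-of-N histogram bin count
#'
#' The number of histogram bins is the square root of the total number of
#' objects detected across all images, rounded to the nearest integer
#' (half away from zero), never below 1.
#'
#' @param n_objects total object count (>= 1).
#' @return integer bin count.
#' @export
bin_count <- function(n_objects) {
  if (length(n_objects) != 1L || is.na(n_objects) || n_objects < 1)
    stop("no objects: cannot build a distribution")
  max(1L, as.integer(floor(sqrt(n_objects) + 0.5)))
}

#' Build a pooled size distribution
#'
#' Pools equivalent radii across all images of a sample, bins them over
#' [min, max] with the square-root-of-N rule (bins closed on the right,
#' lowest bin closed on both sides) and computes mean and SD.
#'
#' @param records a \code{particle_records} data frame (possibly the
#'   concatenation of several images), or a numeric vector of radii in um.
#' @return object of class \code{size_distribution}: radii_um, n_objects,
#'   n_bins, bin_edges, bin_counts, mean_radius_um, sd_radius_um.
#' @export
build_distribution <- function(records) {
  radii <- if (is.data.frame(records)) records$equiv_radius_um else records
  radii <- as.numeric(radii)
  if (length(radii) == 0L) stop("no particle records: cannot build a distribution")
  n <- length(radii)
  nb <- bin_count(n)
  rng <- range(radii)
  edges <- if (diff(rng) == 0) rng[1] + c(-1, 1) * 1e-9
           else seq(rng[1], rng[2], length.out = nb + 1L)
  counts <- graphics::hist(radii, breaks = edges, plot = FALSE,
                           right = TRUE, include.lowest = TRUE)$counts
  structure(list(radii_um = radii, n_objects = n, n_bins = length(counts),
                 bin_edges = edges, bin_counts = counts,
                 mean_radius_um = mean(radii),
                 sd_radius_um = if (n > 1) stats::sd(radii) else 0),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf(
    "Size distribution: n = %d objects, %d bins (sqrt-N rule)\n  radius %.4g +/- %.4g um (mean +/- SD), range [%.4g, %.4g] um\n",
    x$n_objects, x$n_bins, x$mean_radius_um, x$sd_radius_um,
    min(x$radii_um), max(x$radii_um)))
  invisible(x)
}

#' @export
summary.size_distribution <- function(object, ...) {
  c(n = object$n_objects, n_bins = object$n_bins,
    mean_radius_um = object$mean_radius_um, sd_radius_um = object$sd_radius_um)
}

#' Plot a size distribution histogram
#'
#' @param x a \code{size_distribution}.
#' @param diameter plot diameters (2x radius) instead of radii.
#' @param ... passed to \code{barplot}.
#' @export
plot.size_distribution <- function(x, diameter = FALSE, ...) {
  e <- if (diameter) 2 * x$bin_edges else x$bin_edges
  mids <- (e[-1] + e[-length(e)]) / 2
  graphics::barplot(x$bin_counts, names.arg = sprintf("%.2f", mids),
                    space = 0, las = 2,
                    xlab = if (diameter) "diameter (um)" else "radius (um)",
                    ylab = "objects", ...)
  invisible(x)
}

#' Imaged volume of one frame
#'
#' Field-of-view area times chamber height, converted to millilitres:
#' rows x cols x pixel_size^2 (um^2) x height (um) x 1e-12 mL/um^3.
#'
#' @param fov_px c(rows, cols) of the frame.
#' @param pixel_size_um um per pixel.
#' @param chamber_height_um chamber height in um.
#' @return volume in mL.
#' @export
imaged_volume <- function(fov_px, pixel_size_um, chamber_height_um) {
  if (any(c(fov_px, pixel_size_um, chamber_height_um) <= 0))
    stop("all geometry inputs must be positive")
  fov_px[1] * fov_px[2] * pixel_size_um^2 * chamber_height_um * 1e-12
}

#' Estimate particle concentration from per-image counts
#'
#' Concentration is the mean particle count per image divided by the
#' imaged volume per frame, scaled by any dilution applied before imaging.
#' The spread is the SD of per-image counts propagated through the same
#' division (replicate-image SD, the n-image reporting convention).
#'
#' @param per_image_counts integer vector, one count per image.
#' @param volume_mL imaged volume of one frame, mL.
#' @param dilution_factor dilution applied to the sample before imaging.
#' @return object of class \code{concentration_estimate}.
#' @export
estimate_concentration <- function(per_image_counts, volume_mL,
                                   dilution_factor = 1) {
  if (length(per_image_counts) < 1L) stop("need at least one image")
  if (volume_mL <= 0) stop("volume must be positive")
  if (dilution_factor < 1) stop("dilution factor must be >= 1")
  sd_counts <- if (length(per_image_counts) > 1L) stats::sd(per_image_counts)
  else {
    warning("single image: concentration SD is undefined, reported as 0")
    0
  }
  structure(list(mean_count_per_image = mean(per_image_counts),
                 n_images = length(per_image_counts),
                 imaged_volume_mL = volume_mL,
                 dilution_factor = dilution_factor,
                 concentration_per_mL =
                   mean(per_image_counts) / volume_mL * dilution_factor,
                 concentration_sd_per_mL =
                   sd_counts / volume_mL * dilution_factor),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf(
    "Concentration: %.4g +/- %.4g particles/mL (SD over %d images)\n  mean count %.2f / frame, imaged volume %.4g mL, dilution x%g\n",
    x$concentration_per_mL, x$concentration_sd_per_mL, x$n_images,
    x$mean_count_per_image, x$imaged_volume_mL, x$dilution_factor))
  invisible(x)
}
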