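#' Radius distributions for synthetic bubble fields
#'
#' \code{radii_fixed} renders a monodisperse field; \code{radii_lognormal}
#' draws radii from a lognormal, the usual shape of shaken polydisperse
#' lipid microbubble populations.
#'
#' @param r_um fixed radius in micrometres.
#' @param meanlog,sdlog lognormal parameters of the radius in micrometres.
#' @return a radius-distribution description.
#' @export
radii_fixed <- function(r_um) {
  if (r_um <= 0) stop("radius must be positive")
  structure(list(type = "fixed", r_um = r_um), class = "radii_distribution")
}

#' @rdname radii_fixed
#' @export
radii_lognormal <- function(meanlog, sdlog) {
  if (sdlog < 0) stop("sdlog must be non-negative")
  structure(list(type = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "radii_distribution")
}

#' Specification of a synthetic brightfield frame
#'
#' Describes the imaging conditions emulated by the brightfield generator:
#' a thin chamber of known height imaged at a known pixel size, holding a
#' Poisson-count field of bubbles with configurable size distribution,
#' touching aggregates, out-of-focus objects, additive Gaussian noise and a
#' linear illumination gradient.
#'
#' @param field_of_view_px c(rows, cols) of the frame.
#' @param pixel_size_um micrometres per pixel.
#' @param chamber_height_um imaging chamber height (um).
#' @param radii a \code{radii_distribution}.
#' @param target_count_per_image expected (Poisson mean) objects per frame.
#' @param aggregate_fraction fraction of objects placed touching a partner
#'   (centre separation uniform in 1.2-1.8 times the mean of the two radii).
#' @param defocus_fraction fraction of objects rendered with extra blur.
#' @param noise_sd additive Gaussian noise SD, 16-bit intensity units.
#' @param illumination_gradient maximum fractional shading across the frame.
#' @param background_level background intensity, 16-bit units.
#' @param seed RNG seed recorded in the ground truth.
#' @return a \code{brightfield_spec} list.
#' @export
brightfield_spec <- function(field_of_view_px = c(1024L, 1024L),
                             pixel_size_um = 0.16,
                             chamber_height_um = 10,
                             radii = radii_lognormal(log(1.2), 0.4),
                             target_count_per_image = 50,
                             aggregate_fraction = 0,
                             defocus_fraction = 0,
                             noise_sd = 400,
                             illumination_gradient = 0.05,
                             background_level = 30000,
                             seed = 1L) {
  frac <- c(aggregate_fraction, defocus_fraction)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (chamber_height_um <= 0) stop("chamber_height_um must be positive")
  if (target_count_per_image < 0) stop("expected count must be >= 0")
  if (illumination_gradient < 0 || illumination_gradient >= 1)
    stop("illumination_gradient must lie in [0, 1)")
  if (!inherits(radii, "radii_distribution")) stop("radii must be a radii_distribution")
  structure(list(field_of_view_px = as.integer(field_of_view_px),
                 pixel_size_um = pixel_size_um,
                 chamber_height_um = chamber_height_um,
                 radii = radii,
                 target_count_per_image = target_count_per_image,
                 aggregate_fraction = aggregate_fraction,
                 defocus_fraction = defocus_fraction,
                 noise_sd = noise_sd,
                 illumination_gradient = illumination_gradient,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "brightfield_spec")
}

draw_radii <- function(radii, n) {
  switch(radii$type,
         fixed = rep(radii$r_um, n),
         lognormal = stats::rlnorm(n, radii$meanlog, radii$sdlog))
}

# stamp one object onto the intensity matrix, multiplicative on the local
# value. "bubble": dark rim at d = r with slightly brighter core (two-ring
# profile, Gaussian edge softness); "bead": solid dark disk with soft edge.
stamp_object <- function(px, center, r_px, style, softness) {
  nr <- nrow(px); nc <- ncol(px)
  ext <- ceiling(r_px + 4 * softness + 2)
  rs <- max(1L, floor(center[1] - ext)):min(nr, ceiling(center[1] + ext))
  cs <- max(1L, floor(center[2] - ext)):min(nc, ceiling(center[2] + ext))
  d <- sqrt(outer((rs - center[1])^2, (cs - center[2])^2, "+"))
  if (style == "bead") {
    m <- 1 - 0.6 * stats::pnorm((r_px - d) / softness)
  } else {
    rim <- exp(-(d - r_px)^2 / (2 * softness^2))
    core <- stats::pnorm((r_px - 1.5 * softness - d) / softness)
    m <- 1 + 0.15 * core - 0.55 * rim
  }
  px[rs, cs] <- px[rs, cs] * m
  px
}

place_centers <- function(n, nr, nc, r_px, min_sep_factor = 3, rng_margin = 2) {
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      cand <- c(stats::runif(1, r_px[i] + rng_margin, nr - r_px[i] - rng_margin),
                stats::runif(1, r_px[i] + rng_margin, nc - r_px[i] - rng_margin))
      ok <- TRUE
      if (i > 1) {
        prev <- centers[seq_len(i - 1), , drop = FALSE]
        dd <- sqrt((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2)
        ok <- all(dd >= min_sep_factor * (r_px[seq_len(i - 1)] + r_px[i]) / 2 + 2)
      }
      if (ok) break
    }
    centers[i, ] <- cand
  }
  centers
}

render_field <- function(spec, style) {
  set.seed(spec$seed)
  nr <- spec$field_of_view_px[1]; nc <- spec$field_of_view_px[2]
  n <- stats::rpois(1, spec$target_count_per_image)
  radii_um <- draw_radii(spec$radii, n)
  r_px <- radii_um / spec$pixel_size_um
  if (any(r_px > min(nr, nc) / 2))
    stop("object radius ", max(radii_um), " um exceeds half the frame")
  if (n > 0 && any(r_px < 2))
    warning("objects of ~", round(min(r_px), 2),
            " px radius are at the resolution limit for this pixel size")
  n_pairs <- min(floor(n / 2), round(spec$aggregate_fraction * n / 2))
  n_single <- n - 2L * n_pairs
  is_aggregate <- rep(c(FALSE, TRUE), c(n_single, 2L * n_pairs))
  is_defocused <- stats::runif(n) < spec$defocus_fraction

  centers <- matrix(NA_real_, n, 2)
  if (n_single > 0)
    centers[seq_len(n_single), ] <-
      place_centers(n_single, nr, nc, r_px[seq_len(n_single)])
  if (n_pairs > 0) {
    anchor_idx <- n_single + 2L * seq_len(n_pairs) - 1L
    # margin 3.2 r + 4 guarantees the partner (at most 1.8 r away) fits
    # inside the frame, so the drawn separation is never clamped
    anchors <- place_centers(n_pairs, nr, nc,
                             r_px[anchor_idx] * 3.2 + 4, min_sep_factor = 3)
    for (k in seq_len(n_pairs)) {
      i <- n_single + 2L * k - 1L
      j <- i + 1L
      centers[i, ] <- anchors[k, ]
      sep <- stats::runif(1, 1.2, 1.8) * (r_px[i] + r_px[j]) / 2
      ang <- stats::runif(1, 0, 2 * pi)
      centers[j, ] <- anchors[k, ] + sep * c(cos(ang), sin(ang))
      centers[j, ] <- pmin(pmax(centers[j, ], r_px[j] + 2),
                           c(nr, nc) - r_px[j] - 2)
    }
  }

  px <- matrix(spec$background_level, nr, nc)
  if (spec$illumination_gradient > 0) {
    ramp <- 1 - spec$illumination_gradient * (seq_len(nc) - 1) / (nc - 1)
    px <- sweep(px, 2, ramp, "*")
  }
  if (n > 0) {
    softness <- ifelse(is_defocused, 3, 1)
    for (i in seq_len(n))
      px <- stamp_object(px, centers[i, ], r_px[i], style, softness[i])
  }
  if (spec$noise_sd > 0)
    px <- px + stats::rnorm(nr * nc, 0, spec$noise_sd)
  px <- round(pmin(pmax(px, 0), 65535))

  truth <- data.frame(center_row_px = centers[, 1], center_col_px = centers[, 2],
                      radius_um = radii_um, is_aggregate = is_aggregate,
                      is_defocused = is_defocused)
  attr(truth, "seed") <- spec$seed
  list(frame = image_frame(px, 16L, spec$pixel_size_um), truth = truth)
}

#' Render a synthetic brightfield bubble frame
#'
#' Produces a 16-bit frame in which each bubble appears as a dark annulus
#' with a slightly brighter core on a noisy, optionally shaded background —
#' the typical appearance of lipid microbubbles in transmitted light. The
#' object count is Poisson-distributed around the target; every rendered
#' object is recorded in the ground truth.
#'
#' @param spec a \code{brightfield_spec}.
#' @return list with \code{frame} (an \code{image_frame}) and \code{truth}
#'   (data frame: center_row_px, center_col_px, radius_um, is_aggregate,
#'   is_defocused; the seed is attached as an attribute).
#' @export
render_brightfield <- function(spec) {
  if (!inherits(spec, "brightfield_spec")) stop("expected a brightfield_spec")
  render_field(spec, "bubble")
}

#' Render a monodisperse calibration-bead field
#'
#' Polystyrene calibration beads image as solid dark disks; this renders a
#' field of identical beads of the given radius (0.5 um and 1.5 um mirror
#' the 1 um- and 3 um-diameter standards used to calibrate the optical
#' chain). All ground-truth radii equal \code{radius_um} exactly.
#'
#' @param radius_um bead radius in micrometres.
#' @param ... overrides passed to \code{\link{brightfield_spec}}.
#' @return as \code{\link{render_brightfield}}.
#' @export
render_bead_field <- function(radius_um, ...) {
  if (radius_um <= 0) stop("radius must be positive")
  spec <- brightfield_spec(radii = radii_fixed(radius_um), ...)
  render_field(spec, "bead")
}

#' Specification of a synthetic B-mode multi-well frame
#'
#' @param frame_px c(rows, cols) of the frame.
#' @param pixel_pitch_mm millimetres per pixel.
#' @param well_diameter_mm physical well diameter (8 mm bored wells).
#' @param well_centers matrix or list of (row, col) well centres in px.
#' @param background_mean background greyscale level (16-bit units).
#' @param speckle_scale strength of the multiplicative Rayleigh speckle
#'   (0 disables it; the field is normalized to unit mean so the scale
#'   changes variance, not the mean).
#' @param well_intensity_lift additive mean greyscale increase inside each
#'   well (scalar or one value per well; 0 models a control well).
#' @param seed RNG seed.
#' @return a \code{bmode_spec} list.
#' @export
bmode_spec <- function(frame_px = c(512L, 512L),
                       pixel_pitch_mm = 0.05,
                       well_diameter_mm = 8,
                       well_centers,
                       background_mean = 6000,
                       speckle_scale = 0.5,
                       well_intensity_lift = 3000,
                       seed = 1L) {
  if (background_mean < 0) stop("background_mean must be >= 0")
  if (well_diameter_mm <= 0) stop("well_diameter_mm must be positive")
  if (speckle_scale < 0) stop("speckle_scale must be >= 0")
  if (is.list(well_centers)) well_centers <- do.call(rbind, well_centers)
  well_centers <- matrix(well_centers, ncol = 2)
  if (any(well_intensity_lift < 0)) stop("lift must be >= 0")
  lift <- rep_len(well_intensity_lift, nrow(well_centers))
  r_px <- well_diameter_mm / 2 / pixel_pitch_mm
  if (any(well_centers[, 1] - r_px < 1 | well_centers[, 1] + r_px > frame_px[1] |
          well_centers[, 2] - r_px < 1 | well_centers[, 2] + r_px > frame_px[2]))
    stop("well circles must lie fully inside the frame")
  if (nrow(well_centers) > 1) {
    d <- as.matrix(stats::dist(well_centers))
    diag(d) <- Inf
    if (any(d < 2 * r_px)) stop("wells overlap")
  }
  structure(list(frame_px = as.integer(frame_px),
                 pixel_pitch_mm = pixel_pitch_mm,
                 well_diameter_mm = well_diameter_mm,
                 well_centers = well_centers,
                 background_mean = background_mean,
                 speckle_scale = speckle_scale,
                 well_intensity_lift = lift,
                 seed = as.integer(seed)),
            class = "bmode_spec")
}

#' Render a synthetic B-mode multi-well frame
#'
#' Produces a 16-bit speckled frame: a smoothed, unit-mean multiplicative
#' Rayleigh field over a constant background, with the mean intensity
#' inside each well disk raised by its lift. With \code{speckle_scale = 0}
#' the frame is exactly background + lift inside each well.
#'
#' @param spec a \code{bmode_spec}.
#' @return list with \code{frame} (\code{image_frame}) and \code{truth}
#'   (list: \code{wells} data frame with per-well centre, radius_px and
#'   true lift; \code{roi_labels} integer matrix, 0 = background,
#'   k = inside well k).
#' @export
render_bmode_wells <- function(spec) {
  if (!inherits(spec, "bmode_spec")) stop("expected a bmode_spec")
  set.seed(spec$seed)
  nr <- spec$frame_px[1]; nc <- spec$frame_px[2]
  r_px <- spec$well_diameter_mm / 2 / spec$pixel_pitch_mm
  base <- matrix(spec$background_mean, nr, nc)
  roi <- matrix(0L, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(nrow(spec$well_centers))) {
    inside <- (rows - spec$well_centers[k, 1])^2 +
      (cols - spec$well_centers[k, 2])^2 <= r_px^2
    base[inside] <- base[inside] + spec$well_intensity_lift[k]
    roi[inside] <- k
  }
  if (spec$speckle_scale > 0) {
    sigma <- 1
    ray <- sqrt(-2 * sigma^2 * log(stats::runif(nr * nc)))  # Rayleigh(sigma)
    ray <- matrix(ray / (sigma * sqrt(pi / 2)), nr, nc)     # unit mean
    ray <- conv_separable(ray, gaussian_kernel_1d(1))       # short-range corr.
    field <- 1 + spec$speckle_scale * (ray - 1)
    base <- base * pmax(field, 0)
  }
  px <- round(pmin(pmax(base, 0), 65535))
  wells <- data.frame(center_row_px = spec$well_centers[, 1],
                      center_col_px = spec$well_centers[, 2],
                      radius_px = r_px, lift = spec$well_intensity_lift)
  attr(wells, "seed") <- spec$seed
  list(frame = image_frame(px, 16L, NA_real_),
       truth = list(wells = wells, roi_labels = roi))
}

#' Write a rendered fixture to disk
#'
#' Saves the frame as 16-bit TIFF, the ground truth as CSV and the spec as
#' a YAML sidecar, so fixtures interoperate with the batch CLI.
#'
#' @param rendered output of a render function.
#' @param spec the spec used to render it.
#' @param dir output directory (created if needed).
#' @param name basename for the three files.
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(rendered, spec, dir, name = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(name, ".tif"))
  csv <- file.path(dir, paste0(name, "_truth.csv"))
  yml <- file.path(dir, paste0(name, "_spec.yaml"))
  write_image(rendered$frame, tif)
  truth <- if (is.data.frame(rendered$truth)) rendered$truth else rendered$truth$wells
  utils::write.csv(truth, csv, row.names = FALSE)
  yaml::write_yaml(lapply(unclass(spec), function(x)
    if (inherits(x, "radii_distribution")) unclass(x) else x), yml)
  invisible(c(tif, csv, yml))
}
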