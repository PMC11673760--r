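#' Segmentation parameters
#'
#' Tunables of the brightfield segmentation chain. Defaults were calibrated
#' on synthetic monodisperse bead fields (the same procedure used with
#' physical polystyrene size standards): a light blur and the Otsu
#' threshold recover 0.5 um and 1.5 um bead radii within 10 percent at
#' 0.16 um/px, while a heavy blur or the MaxEntropy threshold inflates
#' objects only a few pixels wide. The background structuring radius is
#' kept much larger than any bubble so only slow illumination trends are
#' removed.
#'
#' @param blur_sigma_px Gaussian blur SD in pixels.
#' @param background_radius_px structuring disk radius for the morphological
#'   background estimate (rolling-ball analogue).
#' @param threshold_method "MaxEntropy" (Kapur) or "Otsu".
#' @param outlier_radius_px neighbourhood radius of the outlier-pixel filter.
#' @param outlier_delta intensity deviation from the neighbourhood median
#'   that triggers replacement (8-bit units).
#' @param min_area_px smallest countable object, in pixels.
#' @param watershed_tolerance minimum depth (in distance-map units) of the
#'   saddle between two peaks for the watershed to keep them separate;
#'   0.5 px separates heavily fused pairs without fragmenting single disks.
#' @param polarity "dark" when objects are darker than background (the
#'   brightfield default: bubbles carry a dark rim), "bright" otherwise.
#' @param fill_holes fill interior holes of binarized objects (bubble rims
#'   enclose a brighter core that would otherwise be lost from the area).
#' @param exclude_border border-object rule: "unbiased" (default) drops
#'   objects touching the top or left edge only — the standard unbiased
#'   counting-frame rule, which keeps counts density-faithful; "all" drops
#'   every border-touching object (strictest sizing, undercounts); "none"
#'   keeps everything. Logical TRUE/FALSE are accepted as "all"/"none".
#' @return a \code{segmentation_params} list.
#' @export
segmentation_params <- function(blur_sigma_px = 1,
                                background_radius_px = 50,
                                threshold_method = c("Otsu", "MaxEntropy"),
                                outlier_radius_px = 2,
                                outlier_delta = 50,
                                min_area_px = 4,
                                watershed_tolerance = 0.5,
                                polarity = c("dark", "bright"),
                                fill_holes = TRUE,
                                exclude_border = c("unbiased", "all", "none")) {
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  if (is.logical(exclude_border))
    exclude_border <- if (exclude_border) "all" else "none"
  exclude_border <- match.arg(exclude_border, c("unbiased", "all", "none"))
  if (blur_sigma_px < 0 || background_radius_px < 0 ||
      outlier_radius_px < 0 || outlier_delta < 0 || min_area_px < 0)
    stop("radii, sigma, delta and min_area must be non-negative")
  structure(list(blur_sigma_px = blur_sigma_px,
                 background_radius_px = background_radius_px,
                 threshold_method = threshold_method,
                 outlier_radius_px = outlier_radius_px,
                 outlier_delta = outlier_delta,
                 min_area_px = min_area_px,
                 watershed_tolerance = watershed_tolerance,
                 polarity = polarity,
                 fill_holes = fill_holes,
                 exclude_border = exclude_border),
            class = "segmentation_params")
}

#' Shape-filter acceptance intervals
#'
#' Closed intervals on circularity, solidity and equivalent radius used to
#' reject non-bubble objects (debris, scratches, elongated artifacts).
#'
#' @param circularity_min,circularity_max circularity interval.
#' @param solidity_min,solidity_max solidity interval.
#' @param radius_min_um,radius_max_um equivalent-radius interval (um).
#' @return a \code{filter_criteria} list.
#' @export
filter_criteria <- function(circularity_min = 0, circularity_max = 1,
                            solidity_min = 0, solidity_max = 1,
                            radius_min_um = 0, radius_max_um = Inf) {
  cr <- list(circularity_min = circularity_min,
             circularity_max = circularity_max,
             solidity_min = solidity_min, solidity_max = solidity_max,
             radius_min_um = radius_min_um, radius_max_um = radius_max_um)
  if (cr$circularity_min > cr$circularity_max ||
      cr$solidity_min > cr$solidity_max ||
      cr$radius_min_um > cr$radius_max_um)
    stop("each filter interval must have min <= max")
  structure(cr, class = "filter_criteria")
}

# reflective-boundary separable convolution with a normalized 1-D kernel
conv_separable <- function(px, kernel) {
  h <- (length(kernel) - 1L) / 2L
  reflect_idx <- function(n) {
    # indices 1..n padded by h on each side, reflected without edge repeat
    idx <- c(rev(seq_len(h) + 1L), seq_len(n), n - seq_len(h))
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    idx
  }
  ri <- reflect_idx(nrow(px))
  p <- px[ri, , drop = FALSE]
  out <- matrix(0, nrow(px), ncol(px))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * p[(k - 1L) + seq_len(nrow(px)), , drop = FALSE]
  ci <- reflect_idx(ncol(px))
  p <- out[, ci, drop = FALSE]
  out <- matrix(0, nrow(px), ncol(px))
  for (k in seq_along(kernel))
    out <- out + kernel[k] * p[, (k - 1L) + seq_len(ncol(px)), drop = FALSE]
  out
}

gaussian_kernel_1d <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

#' Gaussian blur with reflective boundary
#'
#' @param frame an \code{image_frame}.
#' @param sigma_px Gaussian SD in pixels; 0 returns the input unchanged.
#' @return blurred \code{image_frame}, clipped to the bit range.
#' @export
gaussian_blur <- function(frame, sigma_px) {
  stopifnot_frame(frame)
  if (sigma_px < 0) stop("sigma must be non-negative")
  if (sigma_px == 0) return(frame)
  out <- conv_separable(frame$pixels, gaussian_kernel_1d(sigma_px))
  out <- pmin(pmax(out, 0), max_intensity(frame))
  image_frame(out, frame$bit_depth, frame$pixel_size_um)
}

#' Morphological background subtraction
#'
#' Estimates the smooth background as the greyscale morphological opening
#' with a disk of the given radius (the rolling-ball analogue) and subtracts
#' it, clipping at zero. Objects *brighter* than background and smaller than
#' the disk survive; the segmentation chain inverts dark-polarity images
#' before this stage.
#'
#' @param frame an \code{image_frame}.
#' @param radius_px structuring disk radius, at least 1 px.
#' @return background-subtracted \code{image_frame}.
#' @export
subtract_background <- function(frame, radius_px) {
  stopifnot_frame(frame)
  if (radius_px < 1) stop("background radius must be at least 1 px")
  maxv <- max_intensity(frame)
  brush <- EBImage::makeBrush(2L * floor(radius_px) + 1L, shape = "disc")
  bg <- EBImage::opening(frame$pixels / maxv, brush) * maxv
  out <- pmax(frame$pixels - bg, 0)
  image_frame(out, frame$bit_depth, frame$pixel_size_um)
}

#' 256-bin intensity histogram of an 8-bit frame
#'
#' @param frame an 8-bit \code{image_frame}.
#' @return integer vector of 256 counts for grey levels 0..255.
#' @export
intensity_histogram <- function(frame) {
  stopifnot_frame(frame)
  if (frame$bit_depth != 8L) stop("histogram thresholds operate on 8-bit frames")
  tabulate(as.integer(round(frame$pixels)) + 1L, nbins = 256L)
}

check_histogram <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0))
    stop("histogram must be 256 non-negative counts")
  if (sum(histogram > 0) < 2L)
    stop("histogram has fewer than 2 occupied bins: no valid split")
}

#' Maximum-entropy (Kapur) threshold
#'
#' Returns the grey level t in 0..255 maximizing the sum of Shannon
#' entropies of the background (levels <= t) and foreground (levels > t)
#' grey-level distributions. Ties break toward the lower level for
#' determinism.
#'
#' @param histogram 256 counts for grey levels 0..255.
#' @return integer threshold level.
#' @export
max_entropy_threshold <- function(histogram) {
  check_histogram(histogram)
  p <- histogram / sum(histogram)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)              # P[t+1] = background mass for split at t
  S <- cumsum(plogp)
  Pf <- 1 - P
  Sf <- sum(plogp) - S
  # H(t) = log P - S/P + log Pf - Sf/Pf; valid only when both classes occupied
  valid <- P > 0 & Pf > 0
  H <- rep(-Inf, 256)
  H[valid] <- log(P[valid]) - S[valid] / P[valid] +
    log(Pf[valid]) - Sf[valid] / Pf[valid]
  which.max(H) - 1L   # which.max returns the first (lowest) maximizer
}

#' Otsu threshold
#'
#' Grey level maximizing the between-class variance of the split at t
#' (background = levels <= t). Ties break toward the lower level.
#'
#' @param histogram 256 counts for grey levels 0..255.
#' @return integer threshold level.
#' @export
otsu_threshold <- function(histogram) {
  check_histogram(histogram)
  p <- histogram / sum(histogram)
  lev <- 0:255
  w0 <- cumsum(p)
  m <- cumsum(p * lev)
  mt <- m[256]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mt * w0[valid] - m[valid])^2 / (w0[valid] * w1[valid])
  which.max(bcv) - 1L
}

#' Binarize a frame at a threshold level
#'
#' @param frame an \code{image_frame}.
#' @param level threshold grey level.
#' @param polarity "bright": objects are pixels strictly above the level;
#'   "dark": strictly below.
#' @return logical matrix mask (TRUE = object).
#' @export
binarize <- function(frame, level, polarity = c("bright", "dark")) {
  stopifnot_frame(frame)
  polarity <- match.arg(polarity)
  if (level < 0 || level > max_intensity(frame)) stop("level out of range")
  if (polarity == "bright") frame$pixels > level else frame$pixels < level
}

#' Watershed declumping of a binary mask
#'
#' Splits connected regions along ridge lines of the Euclidean distance
#' transform, separating touching aggregates into individual objects.
#' Non-touching components keep a single label; label 0 is background.
#'
#' @param mask logical or 0/1 matrix.
#' @param tolerance minimum peak-to-saddle depth for a split.
#' @return integer label matrix.
#' @export
watershed_split <- function(mask, tolerance = 0.5) {
  m <- mask * 1
  if (sum(m) == 0) return(matrix(0L, nrow(m), ncol(m)))
  dm <- EBImage::distmap(m)
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  matrix(as.integer(lab), nrow(m), ncol(m))
}

#' Outlier-pixel removal (conditional median despeckle)
#'
#' Replaces each pixel deviating from its neighbourhood median by more than
#' \code{delta} with that median. On a binary mask use \code{delta < 1} to
#' strip isolated foreground/background pixels.
#'
#' @param x an \code{image_frame} or a numeric/logical matrix (e.g. a mask).
#' @param radius_px neighbourhood radius, at least 1.
#' @param delta deviation triggering replacement, in the units of \code{x}.
#' @return same type as the input.
#' @export
remove_outliers <- function(x, radius_px, delta) {
  if (radius_px < 1) stop("outlier radius must be at least 1")
  is_frame <- inherits(x, "image_frame")
  px <- if (is_frame) x$pixels else x * 1
  maxv <- if (is_frame) max_intensity(x) else max(max(px), 1)
  med <- EBImage::medianFilter(px / maxv, as.integer(radius_px)) * maxv
  out <- ifelse(abs(px - med) > delta, med, px)
  if (is_frame) image_frame(out, x$bit_depth, x$pixel_size_um)
  else if (is.logical(x)) out > 0.5
  else out
}

# Crofton perimeter of a single-object binary submask (padded internally):
# crossing counts with line grids in 4 directions, P = pi/2 * h * mean(crossings)
crofton_perimeter_px <- function(sub) {
  p <- matrix(0L, nrow(sub) + 2L, ncol(sub) + 2L)
  p[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  nr <- nrow(p); nc <- ncol(p)
  n_h <- sum(p[, -1L] != p[, -nc])
  n_v <- sum(p[-1L, ] != p[-nr, ])
  n_d1 <- sum(p[-1L, -1L] != p[-nr, -nc])
  n_d2 <- sum(p[-1L, -nc] != p[-nr, -1L])
  pi / 8 * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

# pixel-count area of the convex hull of pixel centers (Pick-style estimate)
convex_hull_area_px <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2L) return(n)
  pts <- unique(cbind(cols, rows))
  if (nrow(pts) <= 2L) return(n)
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  k <- length(h)
  j <- c(k, seq_len(k - 1L))
  area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
  max(area + per / 2 + 1, n)
}

#' Measure labeled particles
#'
#' Per-label calibrated measurements: area (px count times pixel area),
#' Crofton-estimator perimeter, circularity 4*pi*A/P^2 (clamped to at most 1;
#' single-pixel objects are assigned 1 as a degenerate convention), solidity
#' (area over convex-hull area), equivalent-circle radius sqrt(A/pi), centroid,
#' and a border flag for objects touching the frame edge.
#'
#' @param labels integer label matrix (0 = background).
#' @param pixel_size_um spatial calibration, um per pixel.
#' @return data frame of class \code{particle_records}, one row per label.
#' @export
measure_particles <- function(labels, pixel_size_um) {
  if (is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("a positive pixel_size_um calibration is required")
  ids <- sort(unique(labels[labels > 0]))
  empty <- data.frame(label = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), circularity = numeric(),
                      solidity = numeric(), equiv_radius_um = numeric(),
                      centroid_row_px = numeric(), centroid_col_px = numeric(),
                      on_border = logical())
  if (length(ids) == 0L) return(structure(empty, class = c("particle_records", "data.frame")))
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  lab <- labels[idx]
  out <- lapply(ids, function(id) {
    sel <- lab == id
    r <- rr[sel]; co <- cc[sel]
    a_px <- length(r)
    sub <- matrix(0L, max(r) - min(r) + 1L, max(co) - min(co) + 1L)
    sub[cbind(r - min(r) + 1L, co - min(co) + 1L)] <- 1L
    per_px <- crofton_perimeter_px(sub)
    area_um2 <- a_px * pixel_size_um^2
    per_um <- per_px * pixel_size_um
    circ <- if (a_px <= 1L) 1 else min(1, 4 * pi * area_um2 / per_um^2)
    sol <- min(1, a_px / convex_hull_area_px(r, co))
    data.frame(label = id, area_um2 = area_um2, perimeter_um = per_um,
               circularity = circ, solidity = sol,
               equiv_radius_um = sqrt(area_um2 / pi),
               centroid_row_px = mean(r), centroid_col_px = mean(co),
               on_border = any(r == 1L | r == nr | co == 1L | co == nc))
  })
  res <- do.call(rbind, out)
  structure(res, class = c("particle_records", "data.frame"))
}

#' Filter particle records on shape and size
#'
#' Keeps records whose circularity, solidity and equivalent radius all lie
#' inside the closed intervals of \code{criteria}. Kept/rejected counts are
#' attached as attributes and reported by \code{print}.
#'
#' @param records a \code{particle_records} data frame.
#' @param criteria a \code{filter_criteria} object.
#' @return filtered \code{particle_records}.
#' @export
filter_particles <- function(records, criteria) {
  if (!inherits(criteria, "filter_criteria")) stop("expected filter_criteria")
  if (nrow(records) == 0L) {
    attr(records, "n_kept") <- 0L; attr(records, "n_rejected") <- 0L
    return(records)
  }
  keep <- records$circularity >= criteria$circularity_min &
    records$circularity <= criteria$circularity_max &
    records$solidity >= criteria$solidity_min &
    records$solidity <= criteria$solidity_max &
    records$equiv_radius_um >= criteria$radius_min_um &
    records$equiv_radius_um <= criteria$radius_max_um
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Segment a brightfield frame end to end
#'
#' Runs the full chain in fixed order: 8-bit conversion, polarity inversion
#' for dark objects, Gaussian blur, morphological background subtraction,
#' autothreshold (MaxEntropy or Otsu), binarization (with optional hole
#' filling so dark-rimmed bubbles keep their full footprint), watershed
#' declumping, outlier-pixel removal, border/min-area pruning, particle
#' measurement and shape filtering. Fully deterministic.
#'
#' @param frame a calibrated \code{image_frame}.
#' @param params a \code{segmentation_params} object.
#' @param criteria a \code{filter_criteria} object.
#' @return filtered \code{particle_records}; the threshold level used is
#'   attached as attribute \code{threshold_level}.
#' @export
segment_image <- function(frame, params = segmentation_params(),
                          criteria = filter_criteria()) {
  stopifnot_frame(frame)
  if (is.na(frame$pixel_size_um))
    stop("stage calibration: frame has no pixel_size_um")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  f8 <- stage("convert_to_8bit", convert_to_8bit(frame))
  work <- if (params$polarity == "dark")
    image_frame(255 - f8$pixels, 8L, f8$pixel_size_um) else f8
  # clamp sub-background pits (e.g. bright bubble cores after inversion) at
  # the frame median: the opening estimates the background as a lower
  # envelope, and pits denser than the structuring radius would drag it down
  work <- image_frame(pmax(work$pixels, stats::median(work$pixels)),
                      8L, work$pixel_size_um)
  work <- stage("gaussian_blur", gaussian_blur(work, params$blur_sigma_px))
  work <- stage("subtract_background",
                subtract_background(work, params$background_radius_px))
  h <- stage("histogram", intensity_histogram(work))
  if (sum(h > 0) < 2L) {
    # featureless frame: nothing to split, report no particles
    out <- filter_particles(
      measure_particles(matrix(0L, 2, 2), frame$pixel_size_um), criteria)
    attr(out, "threshold_level") <- NA_integer_
    return(out)
  }
  level <- stage("autothreshold", switch(params$threshold_method,
    MaxEntropy = max_entropy_threshold(h),
    Otsu = otsu_threshold(h)))
  mask <- stage("binarize", binarize(work, level, "bright"))
  if (params$fill_holes)
    mask <- stage("fill_holes",
                  EBImage::fillHull(mask * 1) > 0.5)
  labels <- stage("watershed",
                  watershed_split(mask, params$watershed_tolerance))
  if (params$outlier_radius_px >= 1) {
    clean <- stage("remove_outliers",
                   remove_outliers(labels > 0, params$outlier_radius_px, 0.5))
    labels[!clean] <- 0L
  }
  records <- stage("measure_particles",
                   measure_particles(labels, frame$pixel_size_um))
  if (nrow(records) > 0L) {
    min_area_um2 <- params$min_area_px * frame$pixel_size_um^2
    keep <- records$area_um2 >= min_area_um2
    if (params$exclude_border == "all") {
      keep <- keep & !records$on_border
    } else if (params$exclude_border == "unbiased") {
      # counting-frame rule: reject only objects touching the top or left
      # edge, so every object is counted exactly once across a tiling
      tl <- unique(c(labels[1L, ], labels[, 1L]))
      keep <- keep & !(records$label %in% tl[tl > 0])
    }
    records <- records[keep, , drop = FALSE]
    rownames(records) <- NULL
  }
  out <- stage("filter_particles", filter_particles(records, criteria))
  attr(out, "threshold_level") <- level
  out
}
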