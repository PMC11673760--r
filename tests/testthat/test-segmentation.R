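test_that("8-bit conversion maps the frame range linearly with round-half-away", {
  f8 <- image_frame(matrix(c(0, 100, 255, 7), 2, 2), 8L, 0.2)
  expect_identical(convert_to_8bit(f8), f8)

  f16 <- image_frame(matrix(c(0, 65535), 1, 2), 16L, 0.2)
  expect_equal(convert_to_8bit(f16)$pixels, matrix(c(0, 255), 1, 2))

  # 500 in [0, 1000] -> 127.5 -> rounds away from zero to 128
  f <- image_frame(matrix(c(0, 500, 1000, 250), 2, 2), 16L, 0.2)
  out <- convert_to_8bit(f)
  expect_equal(out$pixels[2, 1], 128)
  expect_equal(out$pixels[1, 2], 255)
  expect_equal(out$pixel_size_um, 0.2)

  const <- image_frame(matrix(1234, 4, 4), 16L)
  expect_warning(z <- convert_to_8bit(const), "constant")
  expect_true(all(z$pixels == 0))
})

test_that("gaussian blur preserves constants, mass, and rejects negative sigma", {
  const <- image_frame(matrix(40, 16, 16), 8L)
  expect_equal(gaussian_blur(const, 3)$pixels, const$pixels)
  expect_identical(gaussian_blur(const, 0), const)
  expect_error(gaussian_blur(const, -1), "non-negative")

  imp <- matrix(0, 41, 41); imp[21, 21] <- 1000
  out <- gaussian_blur(image_frame(imp, 16L), 2)$pixels
  expect_lt(abs(sum(out) - 1000) / 1000, 0.005)
})

test_that("background subtraction equals the brute-force opening oracle", {
  expect_error(subtract_background(image_frame(matrix(5, 8, 8), 8L), 0.5),
               "at least 1 px")
  flat <- image_frame(matrix(120, 32, 32), 8L)
  expect_true(all(subtract_background(flat, 5)$pixels == 0))

  # inverted-polarity path: a dark disk becomes a bright disk that survives
  set.seed(11)
  px <- matrix(round(runif(32 * 32, 100, 110)), 32, 32)
  px[disk_mask(32, 4)] <- px[disk_mask(32, 4)] + 80
  frame <- image_frame(px, 8L)
  got <- subtract_background(frame, 6)$pixels
  brush <- EBImage::makeBrush(13L, "disc")
  off <- which(brush == 1, arr.ind = TRUE) - 7L
  oracle <- pmax(px - brute_opening(px, off), 0)
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_gt(mean(got[disk_mask(32, 3)]), 60)
})

test_that("background subtraction flattens an illumination gradient", {
  n <- 128
  ramp <- matrix(seq(80, 160, length.out = n), n, n, byrow = TRUE)
  px <- ramp
  for (c0 in c(30, 70, 100)) px[disk_mask(n, 4, c(64, c0))] <- 255
  out <- subtract_background(image_frame(round(px), 8L), 30)$pixels
  # opening reproduces a linear ramp exactly away from the frame border,
  # so judge the residual on the interior
  interior <- matrix(FALSE, n, n); interior[32:(n - 31), 32:(n - 31)] <- TRUE
  spots <- disk_mask(n, 8, c(64, 30)) | disk_mask(n, 8, c(64, 70)) |
    disk_mask(n, 8, c(64, 100))
  residual <- out[interior & !spots]
  expect_lt(max(residual) - min(residual), 0.05 * 80)
})

test_that("both autothresholds equal their exhaustive-scan oracles", {
  set.seed(2024)
  for (i in 1:30) {
    h <- random_histogram()
    expect_identical(max_entropy_threshold(h), kapur_scan(h))
    expect_identical(otsu_threshold(h), otsu_scan(h))
  }
  # two deltas at levels 50 and 200: the split must separate them
  # (background = levels <= t, so any t in [50, 199] is separating)
  two <- integer(256); two[51] <- 40; two[201] <- 60
  expect_gte(max_entropy_threshold(two), 50)
  expect_lt(max_entropy_threshold(two), 200)
  expect_gte(otsu_threshold(two), 50)
  expect_lt(otsu_threshold(two), 200)
  one <- integer(256); one[100] <- 50
  expect_error(max_entropy_threshold(one), "occupied bin")
  expect_error(otsu_threshold(one), "occupied bin")
})

test_that("the Kapur criterion is symmetric under histogram mirroring", {
  set.seed(7)
  h <- random_histogram()
  sym <- h + rev(h)  # mirror-symmetric about 127.5
  t1 <- max_entropy_threshold(sym)
  # mirrored split t <-> 254 - t must score identically
  crit <- function(h, t) {
    p <- h / sum(h)
    pb <- p[1:(t + 1)]; pf <- p[(t + 2):256]
    Pb <- sum(pb); Pf <- sum(pf)
    -sum((pb[pb > 0] / Pb) * log(pb[pb > 0] / Pb)) -
      sum((pf[pf > 0] / Pf) * log(pf[pf > 0] / Pf))
  }
  expect_equal(crit(sym, t1), crit(sym, 254L - t1), tolerance = 1e-12)
})

test_that("Otsu lands in the valley of a well-separated bimodal mixture", {
  lev <- 0:255
  h <- round(4000 * dnorm(lev, 60, 8) + 6000 * dnorm(lev, 190, 12))
  t <- otsu_threshold(h)
  expect_gt(t, 60 + 16)
  expect_lt(t, 190 - 24)
})

test_that("binarize respects polarity and is symmetric under inversion", {
  f <- image_frame(matrix(c(10, 100, 200, 30), 2, 2), 8L)
  expect_equal(sum(binarize(f, 255, "bright")), 0)
  expect_equal(binarize(f, 50, "bright"), matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  inv <- image_frame(255 - f$pixels, 8L)
  expect_identical(binarize(f, 50, "bright"), binarize(inv, 205, "dark"))
  expect_error(binarize(f, 300, "bright"), "range")
})

test_that("watershed splits touching disks but never merges components", {
  empty <- matrix(FALSE, 20, 20)
  expect_equal(max(watershed_split(empty)), 0)

  one <- disk_mask(41, 12)
  expect_equal(max(watershed_split(one)), 1)

  # two disks radius 15, centers 24 px apart: overlapping but separable
  m <- disk_mask(80, 15, c(40, 28)) | disk_mask(80, 15, c(40, 52))
  lab <- watershed_split(m)
  expect_equal(max(lab), 2)
  areas <- tabulate(lab[lab > 0])
  expect_true(all(abs(areas / (pi * 15^2) - 1) < 0.2))

  # never merges: label count >= connected component count, random blobs
  set.seed(5)
  for (i in 1:5) {
    blob <- matrix(runif(60 * 60) < 0.4, 60, 60)
    blob <- EBImage::opening(blob * 1, EBImage::makeBrush(3, "box")) > 0
    expect_gte(max(watershed_split(blob)), max(EBImage::bwlabel(blob * 1)))
  }
})

test_that("outlier removal matches a conditional median-filter oracle", {
  m <- matrix(FALSE, 21, 21); m[5, 5] <- TRUE
  expect_equal(sum(remove_outliers(m, 2, 0.5)), 0)

  # solid block: interior is invariant; only the four convex corners sit
  # below their window median and may flip
  block <- matrix(FALSE, 20, 20); block[6:15, 6:15] <- TRUE
  cleaned_block <- remove_outliers(block, 1, 0.5)
  expect_true(all(cleaned_block[7:14, 7:14]))
  expect_lte(sum(cleaned_block != block), 4)

  set.seed(3)
  d <- disk_mask(81, 30)
  salt <- matrix(runif(81 * 81) < 0.01, 81, 81) & !disk_mask(81, 34)
  noisy <- d | salt
  cleaned <- remove_outliers(noisy, 2, 0.5)
  expect_equal(sum(cleaned & salt), 0)           # all isolated pixels gone
  expect_lt(abs(sum(cleaned) - sum(d)) / sum(d), 0.01)

  # greyscale path against the dense median oracle on a small frame
  set.seed(4)
  px <- matrix(round(runif(15 * 15, 0, 255)), 15, 15)
  f <- image_frame(px, 8L)
  med <- brute_median(px, 2)
  oracle <- ifelse(abs(px - med) > 50, med, px)
  got <- remove_outliers(f, 2, 50)$pixels
  # EBImage's windowed median may differ from the square-window oracle on
  # a handful of border-adjacent pixels; interior must agree
  expect_equal(got[4:12, 4:12], oracle[4:12, 4:12], tolerance = 1)
})

test_that("particle measurement recovers analytic disk and ellipse geometry", {
  expect_equal(nrow(measure_particles(matrix(0L, 10, 10), 0.16)), 0)
  expect_error(measure_particles(matrix(0L, 4, 4), -1), "calibration")

  d <- measure_particles(disk_mask(51, 20) * 1L, 0.16)
  expect_equal(d$equiv_radius_um, 3.2, tolerance = 0.16 / 3.2)
  expect_gte(d$circularity, 0.9)
  expect_gte(d$solidity, 0.95)
  expect_false(d$on_border)

  # same area, 3:1 aspect -> strictly lower circularity (isoperimetric)
  e <- measure_particles(ellipse_mask(81, 20 * sqrt(3), 20 / sqrt(3)) * 1L, 0.16)
  expect_lt(e$circularity, d$circularity)
  expect_equal(e$area_um2, d$area_um2, tolerance = 0.02)

  # single-pixel object: degenerate circularity convention
  s <- matrix(0L, 9, 9); s[4, 4] <- 1L
  r <- measure_particles(s, 0.16)
  expect_equal(r$area_um2, 0.16^2)
  expect_equal(r$circularity, 1)
  expect_equal(r$solidity, 1)

  # circularity of rendered disks grows monotonically with radius
  circs <- vapply(c(5, 10, 20, 40), function(r)
    measure_particles(disk_mask(2 * r + 11, r) * 1L, 1)$circularity, numeric(1))
  expect_true(all(diff(circs) > 0))
})

test_that("shape filtering keeps disks, rejects elongated objects, order-free", {
  d <- measure_particles(disk_mask(41, 10) * 1L, 0.16)
  e <- measure_particles(ellipse_mask(61, 10 * sqrt(3), 10 / sqrt(3)) * 1L, 0.16)
  panel <- rbind(d[rep(1, 30), ], e[rep(1, 10), ])
  panel$label <- seq_len(40)
  crit <- filter_criteria(circularity_min = 0.8)

  kept <- filter_particles(panel, crit)
  expect_equal(nrow(kept), 30)
  expect_equal(attr(kept, "n_rejected"), 10)
  expect_true(all(kept$circularity >= 0.8))

  perm <- panel[sample(40), ]
  kept2 <- filter_particles(perm, crit)
  expect_setequal(kept2$label, kept$label)

  expect_equal(nrow(filter_particles(panel, filter_criteria())), 40)
  empty <- panel[0, ]
  expect_equal(nrow(filter_particles(empty, crit)), 0)
  expect_error(filter_criteria(circularity_min = 0.9, circularity_max = 0.1),
               "min <= max")
})

test_that("the full chain is deterministic and recovers a rendered field", {
  blank <- render_brightfield(brightfield_spec(
    field_of_view_px = c(128L, 128L), target_count_per_image = 0,
    noise_sd = 0, illumination_gradient = 0, seed = 1))
  expect_equal(nrow(suppressWarnings(segment_image(blank$frame))), 0)

  bf <- render_brightfield(brightfield_spec(
    field_of_view_px = c(512L, 512L), target_count_per_image = 50,
    radii = radii_fixed(1.5), seed = 7))
  rec1 <- segment_image(bf$frame)
  rec2 <- segment_image(bf$frame)
  expect_identical(rec1, rec2)   # bit-determinism, no RNG in the chain

  truth <- bf$truth
  # count within Poisson noise of the rendered truth (border objects excluded)
  expect_lt(abs(nrow(rec1) - nrow(truth)), 3 * sqrt(nrow(truth)))

  # 50-disk (bead-style) fixture: per-object radius error within one pixel
  bd <- render_bead_field(1.5, field_of_view_px = c(512L, 512L),
                          target_count_per_image = 50, seed = 7)
  recd <- segment_image(bd$frame)
  d2 <- outer(bd$truth$center_row_px, recd$centroid_row_px, "-")^2 +
    outer(bd$truth$center_col_px, recd$centroid_col_px, "-")^2
  nearest <- apply(d2, 1, which.min)
  matched <- sqrt(d2[cbind(seq_len(nrow(bd$truth)), nearest)]) < 5
  err <- abs(recd$equiv_radius_um[nearest[matched]] -
               bd$truth$radius_um[matched])
  expect_lt(stats::median(err), 0.16)

  expect_error(segment_image(image_frame(matrix(5, 8, 8), 8L)), "calibration")
})
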