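# Independent brute-force oracles and analytic mask builders used across
# the suite. These deliberately avoid the code paths they check.

# exhaustive Kapur criterion scan over all 255 candidate splits
kapur_scan <- function(h) {
  p <- h / sum(h)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    pb <- p[1:(t + 1)]; pf <- p[(t + 2):256]
    Pb <- sum(pb); Pf <- sum(pf)
    if (Pb <= 0 || Pf <= 0) next
    eb <- -sum((pb[pb > 0] / Pb) * log(pb[pb > 0] / Pb))
    ef <- -sum((pf[pf > 0] / Pf) * log(pf[pf > 0] / Pf))
    if (eb + ef > best + 1e-12) { best <- eb + ef; bt <- t }
  }
  bt
}

# exhaustive between-class-variance scan
otsu_scan <- function(h) {
  p <- h / sum(h); lev <- 0:255
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- sum(p[1:(t + 1)] * lev[1:(t + 1)]) / w0
    m1 <- sum(p[(t + 2):256] * lev[(t + 2):256]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best + 1e-12) { best <- v; bt <- t }
  }
  bt
}

# greyscale opening by direct min-then-max over an explicit offset set
brute_opening <- function(px, offsets) {
  nr <- nrow(px); nc <- ncol(px)
  erode <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r <- i + offsets[, 1]; c <- j + offsets[, 2]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    erode[i, j] <- min(px[cbind(r[ok], c[ok])])
  }
  dilate <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    r <- i + offsets[, 1]; c <- j + offsets[, 2]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    dilate[i, j] <- max(erode[cbind(r[ok], c[ok])])
  }
  dilate
}

# plain dense median filter over a (2r+1)^2 square window, edges truncated
brute_median <- function(px, radius) {
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rs <- max(1, i - radius):min(nr, i + radius)
    cs <- max(1, j - radius):min(nc, j + radius)
    out[i, j] <- stats::median(px[rs, cs])
  }
  out
}

disk_mask <- function(n, r, center = c((n + 1) / 2, (n + 1) / 2)) {
  x <- matrix(seq_len(n), n, n); y <- t(x)
  (x - center[1])^2 + (y - center[2])^2 <= r^2
}

ellipse_mask <- function(n, a, b, center = c((n + 1) / 2, (n + 1) / 2)) {
  x <- matrix(seq_len(n), n, n); y <- t(x)
  ((x - center[1]) / a)^2 + ((y - center[2]) / b)^2 <= 1
}

# random occupied 256-bin histogram
random_histogram <- function() {
  h <- stats::rpois(256, exp(stats::runif(256, 0, 6)))
  while (sum(h > 0) < 2) h <- stats::rpois(256, exp(stats::runif(256, 0, 6)))
  h
}

# match ground-truth objects to measured records by nearest centroid;
# returns the fraction of truth pairs resolved into two distinct records
resolved_pair_stats <- function(truth, records, match_px) {
  agg <- which(truth$is_aggregate)
  d2 <- outer(truth$center_row_px, records$centroid_row_px, "-")^2 +
    outer(truth$center_col_px, records$centroid_col_px, "-")^2
  nearest <- apply(d2, 1, which.min)
  total <- 0L; resolved <- 0L
  for (k in seq(1, length(agg) - 1, by = 2)) {
    i <- agg[k]; j <- agg[k + 1]
    total <- total + 1L
    resolved <- resolved + as.integer(
      nearest[i] != nearest[j] &&
        sqrt(d2[i, nearest[i]]) < match_px &&
        sqrt(d2[j, nearest[j]]) < match_px)
  }
  c(total = total, resolved = resolved)
}
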