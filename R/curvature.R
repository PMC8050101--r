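#' Segment-wise curvature of a skeleton, normalized to the membrane
#'
#' Each polyline is resampled at uniform arc spacing, lightly smoothed
#' (moving average over `smooth_window` of arc length, circular for closed
#' polylines) to suppress voxel-scale jitter, and cut into consecutive
#' segments of length `seg_len`. The curvature of a segment is the Menger
#' curvature of its three spanning points (start, midpoint, end): the
#' inverse circumradius `kappa = 4 A / (a b c)`. Relative curvature is
#' `kappa_rel = kappa * R_ves`, so 1.0 means the segment follows the
#' membrane exactly and 0 a straight chord.
#'
#' @param skel a [skeleton()][extract_skeleton()].
#' @param geometry a [detect_vesicle()] result (supplies `R_ves`).
#' @param seg_len segment length (um).
#' @param smooth_window smoothing window (um of arc length); 0 disables.
#' @param end_exclusion arc length trimmed from both ends of open polylines
#'   before segmentation (um); curvature next to junctions and free ends is
#'   dominated by reconstruction artefacts.
#' @param bin_width,kappa_max histogram binning of `kappa_rel`.
#' @return An object of class `curvature_result`: `kappa` (per segment,
#'   1/um), `kappa_rel`, `mean`, `sem`, `n_segments`, `n_skipped` (polylines
#'   shorter than `seg_len`), `histogram` (`mids`, `counts`, `breaks`).
#' @export
segment_curvature <- function(skel, geometry, seg_len = 1,
                              smooth_window = 1.5, end_exclusion = 1.5,
                              bin_width = 0.125, kappa_max = 2.5) {
  stopifnot(inherits(skel, "skeleton"))
  R <- geometry$R_ves
  kap <- numeric(0)
  n_skipped <- 0L
  for (q in seq_along(skel$polylines)) {
    p <- skel$polylines[[q]]
    closed <- skel$closed[q]
    len <- sum(sqrt(rowSums(diff(p)^2)))
    if (len < seg_len || nrow(p) < 4) {
      n_skipped <- n_skipped + 1L
      next
    }
    ds <- seg_len / 5
    rp <- .resample_polyline(p, ds, closed)
    if (smooth_window > 0)
      rp <- .smooth_polyline(rp, max(1L, round(smooth_window / ds)), closed)
    if (!closed && end_exclusion > 0) {
      trim <- ceiling(end_exclusion / ds)
      if (nrow(rp) <= 2 * trim + 3) {
        n_skipped <- n_skipped + 1L
        next
      }
      rp <- rp[(trim + 1):(nrow(rp) - trim), , drop = FALSE]
    }
    kap <- c(kap, .menger_segments(rp, ds, seg_len, closed))
  }
  kr <- kap * R
  h <- hist(pmin(kr, kappa_max), breaks = seq(0, kappa_max, by = bin_width),
            plot = FALSE)
  structure(list(kappa = kap, kappa_rel = kr,
                 mean = if (length(kr)) mean(kr) else NA_real_,
                 sem = if (length(kr) > 1) stats::sd(kr) / sqrt(length(kr))
                       else NA_real_,
                 n_segments = length(kr), n_skipped = n_skipped,
                 histogram = list(mids = h$mids, counts = h$counts,
                                  breaks = h$breaks),
                 seg_len = seg_len, R_ves = R),
            class = "curvature_result")
}

#' @export
print.curvature_result <- function(x, ...) {
  cat(sprintf(paste0("curvature_result: %d segments of %g um, mean",
                     " kappa_rel = %.3f +/- %.3f (SEM), %d skipped\n"),
              x$n_segments, x$seg_len, x$mean, x$sem, x$n_skipped))
  invisible(x)
}

# uniform arc-length resampling
.resample_polyline <- function(p, ds, closed = FALSE) {
  if (closed) p <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  keep <- c(TRUE, seg > 1e-12)
  p <- p[keep, , drop = FALSE]
  s <- s[keep]
  tot <- s[length(s)]
  si <- seq(0, tot, by = ds)
  cbind(stats::approx(s, p[, 1], si)$y,
        stats::approx(s, p[, 2], si)$y,
        stats::approx(s, p[, 3], si)$y)
}

# moving-average smoothing; circular for closed curves, shrinking window at
# the ends of open ones
.smooth_polyline <- function(p, w, closed = FALSE) {
  if (w < 2) return(p)
  half <- w %/% 2
  n <- nrow(p)
  if (n <= w + 1) return(p)
  out <- p
  if (closed) {
    # last point duplicates the first; smooth on the unique points
    q <- p[-n, , drop = FALSE]
    m <- nrow(q)
    idx <- function(i) ((i - 1) %% m) + 1
    for (j in 1:3) {
      v <- q[, j]
      acc <- v * 0
      for (o in -half:half) acc <- acc + v[idx(seq_len(m) + o)]
      out[-n, j] <- acc / (2 * half + 1)
    }
    out[n, ] <- out[1, ]
  } else {
    for (j in 1:3) {
      cs <- cumsum(c(0, p[, j]))
      lo <- pmax(1, seq_len(n) - half)
      hi <- pmin(n, seq_len(n) + half)
      out[, j] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    }
  }
  out
}

# Menger curvature of consecutive seg_len spans of an arc-resampled curve
.menger_segments <- function(rp, ds, seg_len, closed = FALSE) {
  n <- nrow(rp)
  step <- max(2L, round(seg_len / ds))
  half <- step %/% 2
  if (n <= step) return(numeric(0))
  starts <- seq(1, n - step, by = step)
  if (length(starts) == 0) return(numeric(0))
  vapply(starts, function(i) {
    a <- rp[i, ]; b <- rp[i + half, ]; c1 <- rp[i + step, ]
    .menger(a, b, c1)
  }, numeric(1))
}

.menger <- function(a, b, c1) {
  ab <- b - a; ac <- c1 - a; bc <- c1 - b
  la <- sqrt(sum(ab^2)); lb <- sqrt(sum(ac^2)); lc <- sqrt(sum(bc^2))
  if (la * lb * lc < 1e-12) return(0)
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
          ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  2 * sqrt(sum(cr^2)) / (la * lb * lc)
}
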