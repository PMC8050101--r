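#' Extract a 3D curve skeleton from the actin channel
#'
#' The tracing pipeline: background subtraction (median), resampling of the
#' anisotropic stack to isotropic voxels (linear interpolation along z),
#' global Otsu threshold, 3D morphological thinning to a one-voxel-wide
#' curve skeleton, conversion of the voxel skeleton to polylines between
#' junctions, pruning of short spurs, and sub-voxel refinement of each
#' polyline point to the transverse intensity centroid of the surrounding
#' tube. Deterministic throughout.
#'
#' @param stack a [vesicle_stack()].
#' @param geometry optional [detect_vesicle()] result; when present, points
#'   farther than `R_ves + 1` um from the centre are discarded as artefacts.
#' @param threshold intensity threshold; `NULL` = Otsu.
#' @param prune_len spur branches shorter than this are removed (um).
#' @param refine logical; sub-voxel centroid refinement on/off.
#' @param refine_sigma Gaussian window sigma of the centroid refinement
#'   (um). Larger windows converge faster along the elongated axial PSF but
#'   bleed intensity from nearby structures at crossings.
#' @return An object of class `skeleton`: `polylines` (list of n x 3
#'   matrices, um, stack coordinates), `closed` (logical per polyline),
#'   `lengths` (um), `voxel_size` (isotropic grid spacing used).
#' @export
extract_skeleton <- function(stack, geometry = NULL, threshold = NULL,
                             prune_len = 1, refine = TRUE,
                             refine_sigma = 0.35) {
  stopifnot(inherits(stack, "vesicle_stack"))
  vol <- stack$actin
  bg <- stats::median(vol)
  vol <- vol - bg
  vol[vol < 0] <- 0
  iso <- .resample_isotropic(vol, stack$z_spacing, stack$voxel_size_xy)
  vx <- stack$voxel_size_xy
  if (max(iso) <= 0) return(.empty_skeleton(vx))
  # extra isotropic smoothing for binarization only: rounds the anisotropic
  # PSF tube so thinning yields a clean 1-voxel centerline; the sub-voxel
  # refinement below reads the unsmoothed volume
  smo <- .gauss_blur3(iso, 0.3, 0.3, vx, vx)
  th <- if (is.null(threshold)) .otsu(smo[smo > 0]) else threshold
  bin <- smo >= th
  if (!any(bin)) return(.empty_skeleton(vx))
  thin <- thin3d_cpp(as.logical(bin), dim(bin))
  dim(thin) <- dim(bin)
  pl <- .trace_polylines(thin, vx, prune_len)
  if (length(pl$polylines) == 0) return(.empty_skeleton(vx))
  if (refine) {
    maps <- .centroid_maps(iso, vx, sigma_w = refine_sigma)
    pl$polylines <- Map(.refine_centerline, pl$polylines, pl$closed,
                        MoreArgs = list(maps = maps, vx = vx))
  }
  if (!is.null(geometry)) {
    keep <- vapply(pl$polylines, function(p) {
      r <- sqrt(rowSums(sweep(p, 2, geometry$center)^2))
      mean(r) <= geometry$R_ves + 1
    }, logical(1))
    pl$polylines <- pl$polylines[keep]
    pl$closed <- pl$closed[keep]
  }
  lens <- vapply(pl$polylines, function(p) {
    l <- sum(sqrt(rowSums(diff(p)^2)))
    l
  }, numeric(1))
  structure(list(polylines = pl$polylines, closed = pl$closed,
                 lengths = lens, voxel_size = vx),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d polylines (%d closed), total %.1f um\n",
              length(x$polylines), sum(x$closed), sum(x$lengths)))
  invisible(x)
}

.empty_skeleton <- function(vx) {
  structure(list(polylines = list(), closed = logical(0),
                 lengths = numeric(0), voxel_size = vx),
            class = "skeleton")
}

# linear interpolation along z onto an isotropic grid
.resample_isotropic <- function(vol, z_spacing, voxel_xy) {
  d <- dim(vol)
  if (abs(z_spacing - voxel_xy) < 1e-9) return(vol)
  zc <- (seq_len(d[1]) - 0.5) * z_spacing
  nz2 <- max(2L, round(d[1] * z_spacing / voxel_xy))
  z2 <- (seq_len(nz2) - 0.5) * voxel_xy
  A <- matrix(0, nz2, d[1])
  for (i in seq_len(nz2)) {
    z <- z2[i]
    if (z <= zc[1]) A[i, 1] <- 1
    else if (z >= zc[d[1]]) A[i, d[1]] <- 1
    else {
      k <- findInterval(z, zc)
      f <- (z - zc[k]) / (zc[k + 1] - zc[k])
      A[i, k] <- 1 - f
      A[i, k + 1] <- f
    }
  }
  array(A %*% matrix(vol, d[1], d[2] * d[3]), c(nz2, d[2], d[3]))
}

# voxel skeleton -> polylines between junctions, with spur pruning
.trace_polylines <- function(thin, vx, prune_len) {
  sel <- which(thin)
  if (length(sel) == 0) return(list(polylines = list(), closed = logical(0)))
  d <- dim(thin)
  zi <- ((sel - 1) %% d[1]) + 1
  yi <- (((sel - 1) %/% d[1]) %% d[2]) + 1
  xi <- ((sel - 1) %/% (d[1] * d[2])) + 1
  n <- length(sel)
  key <- sel
  ord <- order(key)
  # 26-neighbour adjacency via key matching
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ei <- integer(0); ej <- integer(0)
  for (k in seq_len(nrow(offs))) {
    z2 <- zi + offs[k, 1]; y2 <- yi + offs[k, 2]; x2 <- xi + offs[k, 3]
    ok <- z2 >= 1 & z2 <= d[1] & y2 >= 1 & y2 <= d[2] & x2 >= 1 & x2 <= d[3]
    k2 <- (x2 - 1) * d[1] * d[2] + (y2 - 1) * d[1] + z2
    m <- match(k2[ok], key)
    src <- which(ok)[!is.na(m)]
    dst <- m[!is.na(m)]
    sel2 <- src < dst
    ei <- c(ei, src[sel2]); ej <- c(ej, dst[sel2])
  }
  coords <- cbind(xi, yi, zi) * vx - 0.5 * vx  # (x, y, z) um
  elen <- sqrt(rowSums((coords[ei, , drop = FALSE] -
                        coords[ej, , drop = FALSE])^2))
  # drop redundant diagonals: remove long edges that close a triangle
  adj <- vector("list", n)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], ej[k])
    adj[[ej[k]]] <- c(adj[[ej[k]]], ei[k])
  }
  keep <- rep(TRUE, length(ei))
  for (k in order(-elen, ei, ej)) {
    if (elen[k] <= vx * 1.01) break  # axis edges never dropped
    a <- ei[k]; b <- ej[k]
    if (length(intersect(adj[[a]], adj[[b]])) > 0) {
      keep[k] <- FALSE
      adj[[a]] <- setdiff(adj[[a]], b)
      adj[[b]] <- setdiff(adj[[b]], a)
    }
  }
  ei <- ei[keep]; ej <- ej[keep]
  repeat {
    res <- .walk_polylines(n, ei, ej, coords)
    # prune spurs: polylines with a free end shorter than prune_len
    lens <- vapply(res$polylines_idx, function(ii)
      sum(sqrt(rowSums(diff(coords[ii, , drop = FALSE])^2))), numeric(1))
    deg <- tabulate(c(ei, ej), n)
    spur <- vapply(seq_along(res$polylines_idx), function(q) {
      ii <- res$polylines_idx[[q]]
      if (res$closed[q]) return(FALSE)
      (deg[ii[1]] == 1 || deg[ii[length(ii)]] == 1) && lens[q] < prune_len
    }, logical(1))
    if (!any(spur) || all(spur)) break
    # remove spur edges and re-trace (junction chains re-merge)
    drop_v <- unlist(lapply(res$polylines_idx[spur], function(ii) {
      # keep the junction end so the main structure stays intact
      if (deg[ii[1]] == 1) ii[-length(ii)] else ii[-1]
    }))
    kill <- ei %in% drop_v | ej %in% drop_v
    if (!any(kill)) break
    ei <- ei[!kill]; ej <- ej[!kill]
  }
  list(polylines = lapply(res$polylines_idx, function(ii)
         coords[ii, , drop = FALSE]),
       closed = res$closed)
}

# split the voxel graph into maximal degree-2 chains
.walk_polylines <- function(n, ei, ej, coords) {
  deg <- tabulate(c(ei, ej), n)
  adj <- vector("list", n)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], k)
    adj[[ej[k]]] <- c(adj[[ej[k]]], k)
  }
  other <- function(k, v) if (ei[k] == v) ej[k] else ei[k]
  used <- rep(FALSE, length(ei))
  polylines <- list(); closed <- logical(0)
  nodes <- which(deg != 2 & deg > 0)
  walk <- function(v0, k0) {
    path <- v0
    k <- k0; v <- v0
    repeat {
      used[k] <<- TRUE
      v <- other(k, v)
      path <- c(path, v)
      if (deg[v] != 2) break
      nk <- adj[[v]][!used[adj[[v]]]]
      if (length(nk) == 0) break
      k <- nk[1]
    }
    path
  }
  for (v0 in nodes)
    for (k0 in adj[[v0]]) {
      if (used[k0]) next
      path <- walk(v0, k0)
      polylines <- c(polylines, list(path))
      closed <- c(closed, path[1] == path[length(path)])
    }
  # components that are pure cycles (every vertex degree 2)
  remaining <- which(!used)
  for (k0 in remaining) {
    if (used[k0]) next
    v0 <- ei[k0]
    path <- walk(v0, k0)
    polylines <- c(polylines, list(path))
    closed <- c(closed, path[1] == path[length(path)])
  }
  list(polylines_idx = polylines, closed = closed)
}

# Gaussian-window intensity centroid fields: the centroid of I(q) weighted
# by a Gaussian around p is (G*(I q))(p) / (G*I)(p), so four blurred
# volumes turn every refinement iteration into cheap trilinear lookups.
.centroid_maps <- function(iso, vx, sigma_w = 0.5) {
  d <- dim(iso)
  zc <- (seq_len(d[1]) - 0.5) * vx
  yc <- (seq_len(d[2]) - 0.5) * vx
  xc <- (seq_len(d[3]) - 0.5) * vx
  Zg <- array(zc, d)
  Yg <- aperm(array(yc, c(d[2], d[1], d[3])), c(2, 1, 3))
  Xg <- aperm(array(xc, c(d[3], d[1], d[2])), c(2, 3, 1))
  bl <- function(v) .gauss_blur3(v, sigma_w, sigma_w, vx, vx)
  list(W = bl(iso), WX = bl(iso * Xg), WY = bl(iso * Yg),
       WZ = bl(iso * Zg))
}

# vectorized trilinear interpolation of a (z,y,x) array at um points
.interp3 <- function(arr, p, vx) {
  d <- dim(arr)
  u <- cbind(p[, 3] / vx + 0.5, p[, 2] / vx + 0.5, p[, 1] / vx + 0.5)
  i0 <- pmax(1, pmin(floor(u), rep(d, each = nrow(u)) - 1))
  dim(i0) <- dim(u)
  f <- pmin(pmax(u - i0, 0), 1)
  dim(f) <- dim(u)
  out <- numeric(nrow(p))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    lin <- (i0[, 3] + cx - 1) * d[1] * d[2] + (i0[, 2] + cy - 1) * d[1] +
      (i0[, 1] + cz)
    w <- (if (cz) f[, 1] else 1 - f[, 1]) *
         (if (cy) f[, 2] else 1 - f[, 2]) *
         (if (cx) f[, 3] else 1 - f[, 3])
    out <- out + w * arr[lin]
  }
  out
}

# move each polyline point to the Gaussian-window intensity centroid of its
# neighbourhood; the tangential component of the correction is projected
# out so points do not slide along the curve
.refine_centerline <- function(p, closed, maps, vx, iters = 6) {
  np <- nrow(p)
  if (np < 3) return(p)
  for (it in seq_len(iters)) {
    tans <- rbind(p[2, ] - p[1, ],
                  p[3:np, , drop = FALSE] - p[1:(np - 2), , drop = FALSE],
                  p[np, ] - p[np - 1, ])
    if (closed) {
      tans[1, ] <- p[2, ] - p[np - 1, ]
      tans[np, ] <- tans[1, ]
    }
    tn <- sqrt(rowSums(tans^2)); tn[tn < 1e-12] <- 1
    tans <- tans / tn
    w <- .interp3(maps$W, p, vx)
    cen <- cbind(.interp3(maps$WX, p, vx), .interp3(maps$WY, p, vx),
                 .interp3(maps$WZ, p, vx)) / pmax(w, 1e-12)
    delta <- cen - p
    delta <- delta - tans * rowSums(delta * tans)
    delta[w <= 1e-9, ] <- 0
    p <- p + delta
    if (closed) p[np, ] <- p[1, ]
  }
  p
}
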