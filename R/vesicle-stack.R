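#' Vesicle z-stack container
#'
#' A 3D fluorescence stack of one vesicle: an actin channel (required), an
#' optional membrane channel, and the voxel calibration. Arrays are indexed
#' `[z, y, x]`; voxel centres sit at `(index - 0.5) * spacing` so physical
#' coordinates start at the grid corner (0, 0, 0).
#'
#' @param actin numeric 3D array (z, y, x), non-negative.
#' @param membrane optional 3D array, same dimensions.
#' @param voxel_size_xy lateral voxel size (um).
#' @param z_spacing axial slice interval (um); confocal stacks of vesicles
#'   are typically taken at 0.5 um.
#' @param metadata free-form list; the synthetic generator stores its ground
#'   truth here.
#' @return An object of class `vesicle_stack`.
#' @export
vesicle_stack <- function(actin, membrane = NULL, voxel_size_xy = 0.2,
                          z_spacing = 0.5, metadata = list()) {
  stopifnot(length(dim(actin)) == 3)
  if (min(actin) < 0) stop("vesicle_stack: negative intensities")
  if (!is.null(membrane)) {
    stopifnot(identical(dim(membrane), dim(actin)))
    if (min(membrane) < 0) stop("vesicle_stack: negative intensities")
  }
  if (voxel_size_xy <= 0 || z_spacing <= 0)
    stop("vesicle_stack: calibrations must be positive")
  structure(list(actin = actin, membrane = membrane,
                 voxel_size_xy = voxel_size_xy, z_spacing = z_spacing,
                 metadata = metadata),
            class = "vesicle_stack")
}

#' @export
print.vesicle_stack <- function(x, ...) {
  d <- dim(x$actin)
  cat(sprintf(paste0("vesicle_stack: %d slices of %d x %d (%.2f um xy,",
                     " %.2f um z)%s\n"),
              d[1], d[2], d[3], x$voxel_size_xy, x$z_spacing,
              if (is.null(x$membrane)) "" else ", membrane channel"))
  invisible(x)
}

# physical coordinates of voxel centres along each axis
.stack_axes <- function(stack) {
  d <- dim(stack$actin)
  list(z = (seq_len(d[1]) - 0.5) * stack$z_spacing,
       y = (seq_len(d[2]) - 0.5) * stack$voxel_size_xy,
       x = (seq_len(d[3]) - 0.5) * stack$voxel_size_xy)
}

#' Write / read a vesicle stack as multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float TIFF per channel (`<base>_actin.tif`,
#' `<base>_membrane.tif`), pages = z slices, and `<base>_meta.json` holding
#' the voxel calibration and any generator metadata.
#'
#' @param stack a [vesicle_stack()]; @param base path prefix (no extension).
#' @return `base` invisibly; [read_stack()] returns the `vesicle_stack`.
#' @export
write_stack <- function(stack, base) {
  sc <- max(stack$actin, 1e-12)
  pages <- lapply(seq_len(dim(stack$actin)[1]),
                  function(k) stack$actin[k, , ] / sc)
  tiff::writeTIFF(pages, paste0(base, "_actin.tif"), bits.per.sample = 32)
  msc <- NA
  if (!is.null(stack$membrane)) {
    msc <- max(stack$membrane, 1e-12)
    pages <- lapply(seq_len(dim(stack$membrane)[1]),
                    function(k) stack$membrane[k, , ] / msc)
    tiff::writeTIFF(pages, paste0(base, "_membrane.tif"),
                    bits.per.sample = 32)
  }
  meta <- list(voxel_size_xy = stack$voxel_size_xy,
               z_spacing = stack$z_spacing,
               actin_scale = sc, membrane_scale = msc,
               metadata = stack$metadata)
  jsonlite::write_json(meta, paste0(base, "_meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(base)
}

#' @rdname write_stack
#' @export
read_stack <- function(base) {
  meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                              simplifyVector = TRUE)
  rd <- function(path, scale) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]] * scale
    arr
  }
  actin <- rd(paste0(base, "_actin.tif"), meta$actin_scale)
  membrane <- NULL
  if (file.exists(paste0(base, "_membrane.tif")))
    membrane <- rd(paste0(base, "_membrane.tif"), meta$membrane_scale)
  vesicle_stack(actin, membrane, meta$voxel_size_xy, meta$z_spacing,
                if (is.null(meta$metadata)) list() else meta$metadata)
}

# separable 3D Gaussian blur; sigmas in physical units, one per axis (z,y,x)
.gauss_blur3 <- function(vol, sigma_z, sigma_xy, z_spacing, voxel_xy) {
  d <- dim(vol)
  kmat <- function(n, sigma, spacing) {
    if (sigma <= 0) return(NULL)
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-((i - j) * spacing)^2 / (2 * sigma^2)))
    K / rowSums(K)
  }
  Kz <- kmat(d[1], sigma_z, z_spacing)
  Ky <- kmat(d[2], sigma_xy, voxel_xy)
  Kx <- kmat(d[3], sigma_xy, voxel_xy)
  m <- matrix(vol, d[1], d[2] * d[3])
  if (!is.null(Kz)) m <- Kz %*% m
  vol <- array(m, d)
  if (!is.null(Ky)) {
    v2 <- aperm(vol, c(2, 1, 3))  # (y, z, x)
    m <- Ky %*% matrix(v2, d[2], d[1] * d[3])
    vol <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  }
  if (!is.null(Kx)) {
    v2 <- aperm(vol, c(3, 1, 2))  # (x, z, y)
    m <- Kx %*% matrix(v2, d[3], d[1] * d[2])
    vol <- aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  vol
}

# Otsu threshold on a 256-bin histogram
.otsu <- function(v) {
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  h <- as.numeric(tabulate(pmin(256L, 1L + floor((v - lo) / (hi - lo) * 256)),
                           256L))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(256))
  n <- w[256]; mtot <- mu[256]
  w1 <- w[-256]; mu1 <- mu[-256]
  between <- (mtot * w1 - n * mu1)^2 / (w1 * (n - w1))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  lo + (k / 256) * (hi - lo)
}

# trilinear scatter deposition of weighted points onto a (z,y,x) grid
.deposit <- function(d, pts, w, z_spacing, voxel_xy) {
  uz <- pts[, 3] / z_spacing + 0.5
  uy <- pts[, 2] / voxel_xy + 0.5
  ux <- pts[, 1] / voxel_xy + 0.5
  iz <- floor(uz); iy <- floor(uy); ix <- floor(ux)
  fz <- uz - iz; fy <- uy - iy; fx <- ux - ix
  acc <- numeric(prod(d))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    zz <- iz + cz; yy <- iy + cy; xx <- ix + cx
    ww <- w * (if (cz) fz else 1 - fz) * (if (cy) fy else 1 - fy) *
      (if (cx) fx else 1 - fx)
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    if (!any(ok)) next
    lin <- (xx[ok] - 1) * d[1] * d[2] + (yy[ok] - 1) * d[1] + zz[ok]
    s <- rowsum(ww[ok], lin)
    acc[as.numeric(rownames(s))] <- acc[as.numeric(rownames(s))] + s[, 1]
  }
  array(acc, d)
}
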