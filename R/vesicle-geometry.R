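#' Detect vesicle geometry by sphere fitting
#'
#' Fits a sphere to the membrane channel (preferred) or, failing that, to
#' the outermost above-threshold actin voxels. The fit is the algebraic
#' least-squares sphere (linear in centre and radius), which is exact for
#' noise-free shells and robust to the symmetric spread a PSF introduces.
#'
#' @param stack a [vesicle_stack()].
#' @param threshold intensity threshold; `NULL` uses Otsu's method on the
#'   chosen channel.
#' @return An object of class `vesicle_geometry`: `center` (x, y, z um),
#'   `R_ves` (um), `residual` (rms um), `channel` used. A warning is issued
#'   if the fitted sphere pokes out of the stack.
#' @export
detect_vesicle <- function(stack, threshold = NULL) {
  stopifnot(inherits(stack, "vesicle_stack"))
  use_membrane <- !is.null(stack$membrane)
  vol <- if (use_membrane) stack$membrane else stack$actin
  channel <- if (use_membrane) "membrane" else "actin"
  if (max(vol) <= 0)
    stop("detect_vesicle: no signal in ", channel, " channel")
  # Otsu alone fails when 98% of voxels are dim background: the threshold
  # can land inside the noise. Anchor it to the bright tail as well.
  th <- if (is.null(threshold)) {
    pos <- vol[vol > 0]
    max(.otsu(vol), 0.5 * stats::quantile(pos, 0.9995))
  } else threshold
  sel <- which(vol >= th)
  if (length(sel) < 30)
    stop("detect_vesicle: too few voxels above threshold in ", channel,
         " channel")
  ax <- .stack_axes(stack)
  d <- dim(vol)
  zi <- ((sel - 1) %% d[1]) + 1
  yi <- (((sel - 1) %/% d[1]) %% d[2]) + 1
  xi <- ((sel - 1) %/% (d[1] * d[2])) + 1
  P <- cbind(ax$x[xi], ax$y[yi], ax$z[zi])
  if (!use_membrane) P <- .outer_hull_points(P, xi, yi, zi)
  fit <- .fit_sphere(P)
  # trimmed refit: isolated noise voxels far from the shell are discarded
  for (it in 1:2) {
    r <- sqrt(rowSums(sweep(P, 2, fit$center)^2))
    keep <- abs(r - fit$R) <= pmax(2 * fit$residual, 0.4)
    if (sum(keep) < 30 || all(keep)) break
    P <- P[keep, , drop = FALSE]
    fit <- .fit_sphere(P)
  }
  if (any(fit$center - fit$R < 0) ||
      fit$center[1] + fit$R > max(ax$x) + stack$voxel_size_xy ||
      fit$center[2] + fit$R > max(ax$y) + stack$voxel_size_xy ||
      fit$center[3] + fit$R > max(ax$z) + stack$z_spacing)
    warning("detect_vesicle: fitted sphere extends beyond the stack")
  structure(list(center = fit$center, R_ves = fit$R,
                 residual = fit$residual, channel = channel),
            class = "vesicle_geometry")
}

#' @export
print.vesicle_geometry <- function(x, ...) {
  cat(sprintf(paste0("vesicle_geometry: R = %.2f um, centre (%.2f, %.2f,",
                     " %.2f) um, rms residual %.3f um [%s]\n"),
              x$R_ves, x$center[1], x$center[2], x$center[3], x$residual,
              x$channel))
  invisible(x)
}

# algebraic sphere fit: |p|^2 = 2 c.p + (R^2 - |c|^2)
.fit_sphere <- function(P) {
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  coef <- qr.coef(qr(A), b)
  ctr <- coef[1:3]
  R <- sqrt(coef[4] + sum(ctr^2))
  r <- sqrt(rowSums(sweep(P, 2, ctr)^2))
  list(center = unname(ctr), R = unname(R),
       residual = sqrt(mean((r - R)^2)))
}

# outer extremes of the foreground per grid line: a cheap hull stand-in so
# interior actin (chords, fills) does not drag the sphere fit inward
.outer_hull_points <- function(P, xi, yi, zi) {
  keep <- logical(nrow(P))
  scans <- list(list(key = paste(xi, yi), col = 3),
                list(key = paste(xi, zi), col = 2),
                list(key = paste(yi, zi), col = 1))
  for (sc in scans) {
    for (f in list(which.max, which.min)) {
      idx <- vapply(split(seq_along(sc$key), sc$key),
                    function(ii) ii[f(P[ii, sc$col])], integer(1))
      keep[idx] <- TRUE
    }
  }
  P[keep, , drop = FALSE]
}
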