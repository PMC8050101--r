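#' Scene specification for synthetic vesicle stacks
#'
#' Describes one vesicle and the parametric actin geometry it contains.
#' Curve-based kinds mirror the morphologies seen in cytoskeletal vesicles:
#' a membrane-hugging ring (great circle), a ring with a small gap, a ring
#' with a side branch, a cortex of disjoint membrane arcs, and straight
#' chords spanning the lumen. Volumetric control kinds anchor the
#' membrane-proximity index: a thin shell on the membrane, a small central
#' blob, and a uniform fill.
#'
#' @param kind one of `"ring"`, `"ring_with_gap"`, `"ring_with_branch"`,
#'   `"cortex_arcs"`, `"straight_chords"`, `"uniform_fill"`,
#'   `"center_blob"`, `"membrane_shell"`.
#' @param R_ves vesicle radius (um). Vesicles of 15--20 um diameter, i.e.
#'   `R_ves` 7.5--10, match the analyzed population.
#' @param gap_fraction gap as a fraction of the circumference
#'   (`ring_with_gap`).
#' @param branch_length side-branch arc length (um, `ring_with_branch`).
#' @param n_arcs number of cortex arcs; @param arc_length mean arc length
#'   (um).
#' @param n_chords number of straight chords.
#' @param blob_radius radius of the central blob (um).
#' @param intensity fluorophore line (or volume) density scale.
#' @param seed RNG seed used by [make_geometry()] for random orientations.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(kind = c("ring", "ring_with_gap", "ring_with_branch",
                                "cortex_arcs", "straight_chords",
                                "uniform_fill", "center_blob",
                                "membrane_shell"),
                       R_ves = 8, gap_fraction = 0.05, branch_length = 3,
                       n_arcs = 8, arc_length = 5, n_chords = 5,
                       blob_radius = 0.5, intensity = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (R_ves <= 0) stop("scene_spec: R_ves must be positive")
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("scene_spec: gap_fraction must be in [0, 1)")
  if (blob_radius >= R_ves)
    stop("scene_spec: blob_radius must be smaller than R_ves")
  if (branch_length <= 0 || arc_length <= 0 || intensity <= 0)
    stop("scene_spec: lengths and intensity must be positive")
  structure(list(kind = kind, R_ves = R_ves, gap_fraction = gap_fraction,
                 branch_length = branch_length, n_arcs = n_arcs,
                 arc_length = arc_length, n_chords = n_chords,
                 blob_radius = blob_radius, intensity = intensity,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# random orthonormal frame (u, v, w)
.rand_frame <- function() {
  repeat {
    u <- stats::rnorm(3)
    nu <- sqrt(sum(u^2))
    if (nu > 1e-6) break
  }
  u <- u / nu
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(u = u, v = v, w = w)
}

# smallest distance between a candidate curve and a list of curves
# (computed on subsampled points; curves are densely sampled)
.min_curve_distance <- function(cand, curves) {
  if (length(curves) == 0) return(Inf)
  a <- cand[seq(1, nrow(cand), by = 4), , drop = FALSE]
  dmin <- Inf
  for (cv in curves) {
    b <- cv[seq(1, nrow(cv), by = 4), , drop = FALSE]
    cross <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    dmin <- min(dmin, sqrt(max(0, min(cross))))
  }
  dmin
}

# great-circle arc of given arc length from point p along unit tangent t
.geodesic <- function(R, p, t, len, ds = 0.05) {
  s <- seq(0, len, by = ds)
  th <- s / R
  outer(cos(th), p) + outer(sin(th), t)
}

#' Generate the parametric curves (or volume descriptor) of a scene
#'
#' Curves are sampled at sub-voxel arc spacing (0.05 um) in vesicle-centred
#' coordinates (um). The returned ground truth records the true topology
#' class, true segment curvature relative to the membrane, and the true
#' radial position of the signal, so that every quantification stage can be
#' validated against it.
#'
#' @param spec a [scene_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return list with `curves` (list of n x 3 matrices, um; empty for
#'   volumetric kinds), `volumetric` (`NULL` or the kind name) and `truth`
#'   (list: `class` in ring/ring_like/none, `kappa_rel`, `radial` = typical
#'   r/R_ves of the signal).
#' @export
make_geometry <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"))
  R <- spec$R_ves
  with_seed(seed, function() {
    curves <- list()
    volumetric <- NULL
    truth <- list(class = "none", kappa_rel = NA_real_, radial = NA_real_)
    fr <- .rand_frame()
    if (spec$kind == "ring") {
      th <- seq(0, 2 * pi, by = 0.05 / R)
      curves <- list(R * (outer(cos(th), fr$u) + outer(sin(th), fr$v)))
      truth <- list(class = "ring", kappa_rel = 1, radial = 1)
    } else if (spec$kind == "ring_with_gap") {
      th <- seq(0, 2 * pi * (1 - spec$gap_fraction), by = 0.05 / R)
      curves <- list(R * (outer(cos(th), fr$u) + outer(sin(th), fr$v)))
      truth <- list(class = if (spec$gap_fraction < 0.1) "ring_like"
                            else "none",
                    kappa_rel = 1, radial = 1)
    } else if (spec$kind == "ring_with_branch") {
      th <- seq(0, 2 * pi, by = 0.05 / R)
      ring <- R * (outer(cos(th), fr$u) + outer(sin(th), fr$v))
      # branch leaves the ring at u along a tilted great circle
      beta <- pi / 4
      tb <- cos(beta) * fr$v + sin(beta) * fr$w
      branch <- R * .geodesic(R, fr$u, tb, spec$branch_length)
      curves <- list(ring, branch)
      truth <- list(class = "ring_like", kappa_rel = 1, radial = 1)
    } else if (spec$kind == "cortex_arcs") {
      # rejection sampling keeps the arcs disjoint: bundles closer than the
      # PSF width would image as one structure
      tries <- 0
      while (length(curves) < spec$n_arcs && tries < 200) {
        tries <- tries + 1
        f2 <- .rand_frame()
        len <- spec$arc_length * stats::runif(1, 0.6, 1.4)
        len <- min(len, 0.9 * 2 * pi * R)
        cand <- R * .geodesic(R, f2$u, f2$v, len)
        if (.min_curve_distance(cand, curves) > min(2.0, 0.28 * R))
          curves[[length(curves) + 1]] <- cand
      }
      if (length(curves) < spec$n_arcs)
        stop("make_geometry: could not place ", spec$n_arcs,
             " disjoint arcs; reduce n_arcs or arc_length")
      truth <- list(class = "none", kappa_rel = 1, radial = 1)
    } else if (spec$kind == "straight_chords") {
      tries <- 0
      while (length(curves) < spec$n_chords && tries < 200) {
        tries <- tries + 1
        f2 <- .rand_frame()
        # chord at offset h from centre, inset so ends stay inside
        h <- stats::runif(1, 0.2, 0.6) * R
        half <- sqrt(R^2 - h^2) - 0.3
        if (half <= 0.5) half <- 0.5
        s <- seq(-half, half, by = 0.05)
        cand <- outer(rep(1, length(s)), h * f2$u) + outer(s, f2$v)
        if (.min_curve_distance(cand, curves) > min(2.5, 0.33 * R))
          curves[[length(curves) + 1]] <- cand
      }
      if (length(curves) < spec$n_chords)
        stop("make_geometry: could not place ", spec$n_chords,
             " separated chords; reduce n_chords")
      truth <- list(class = "none", kappa_rel = 0,
                    radial = NA_real_)
    } else {
      volumetric <- spec$kind
      truth <- switch(spec$kind,
        uniform_fill = list(class = "none", kappa_rel = NA_real_,
                            radial = NA_real_),
        center_blob = list(class = "none", kappa_rel = NA_real_,
                           radial = 0),
        membrane_shell = list(class = "none", kappa_rel = NA_real_,
                              radial = 1))
    }
    for (cv in curves)
      if (any(sqrt(rowSums(cv^2)) > R + 1e-6))
        stop("make_geometry: curve leaves the vesicle")
    list(curves = curves, volumetric = volumetric, truth = truth,
         spec = spec)
  })
}
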