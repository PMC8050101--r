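#' Ring-formation probability over a parameter grid
#'
#' Runs `n_replicates` independently seeded simulations for every condition
#' (row) of `param_grid`, classifies the final snapshot of each run with
#' [classify_ring()], and reports the fraction of replicates that formed a
#' ring or ring-like structure together with a Clopper--Pearson 95% CI.
#' Replicates that abort are excluded from the denominator and flagged.
#'
#' @param param_grid data.frame whose columns are [sim_params()] arguments
#'   (e.g. `R`, `L`, `boundary_mode`); one row per condition.
#' @param n_replicates replicates per condition.
#' @param master_seed integer; per-replicate seeds are drawn from it, so the
#'   whole sweep is reproducible.
#' @param bundling_distance merge radius for [build_bundle_graph()];
#'   `NULL` uses each condition's cross-link range `r_c`.
#' @param classify_fun classifier applied to each bundle graph; swap in a
#'   stub for plumbing tests. Must return a `ring_report`-like list with a
#'   `classification` field.
#' @param base_args named list of [sim_params()] arguments shared by all
#'   conditions (grid columns override).
#' @param on_replicate optional callback
#'   `function(condition_row, replicate, seed, traj, report)` invoked after
#'   each replicate (used by the CLI to write per-replicate reports and
#'   projections).
#' @param verbose print one line per replicate to stderr.
#' @return data.frame: the grid columns plus `n_ok`, `n_failed`, `n_ring`,
#'   `n_ring_like`, `p_ring_like` (= P(ring union ring_like)), `ci_lo`,
#'   `ci_hi`. The per-replicate classifications are attached as attribute
#'   `"replicates"`.
#' @export
ring_probability <- function(param_grid, n_replicates, master_seed = 1,
                             bundling_distance = NULL,
                             classify_fun = classify_ring,
                             base_args = list(), on_replicate = NULL,
                             verbose = FALSE) {
  stopifnot(is.data.frame(param_grid), nrow(param_grid) >= 1)
  seeds <- with_seed(master_seed, function()
    matrix(sample.int(.Machine$integer.max - 1,
                      nrow(param_grid) * n_replicates),
           nrow(param_grid), n_replicates))
  rows <- list()
  reps <- list()
  for (ci in seq_len(nrow(param_grid))) {
    cond <- as.list(param_grid[ci, , drop = FALSE])
    classes <- character(0)
    n_failed <- 0L
    for (ri in seq_len(n_replicates)) {
      args <- utils::modifyList(base_args, cond)
      args$seed <- seeds[ci, ri]
      params <- do.call(sim_params, args)
      traj <- run_simulation(params)
      if (traj$aborted) {
        n_failed <- n_failed + 1L
        reps[[length(reps) + 1]] <- cbind(param_grid[ci, , drop = FALSE],
                                          replicate = ri,
                                          seed = seeds[ci, ri],
                                          classification = "failed")
        next
      }
      bd <- if (is.null(bundling_distance)) params$r_c else bundling_distance
      rep_cls <- classify_fun(build_bundle_graph(final_snapshot(traj), bd))
      classes <- c(classes, rep_cls$classification)
      if (!is.null(on_replicate))
        on_replicate(param_grid[ci, , drop = FALSE], ri, seeds[ci, ri],
                     traj, rep_cls)
      if (verbose)
        message(sprintf("condition %d replicate %d [seed %d]: %s",
                        ci, ri, seeds[ci, ri], rep_cls$classification))
      reps[[length(reps) + 1]] <- cbind(param_grid[ci, , drop = FALSE],
                                        replicate = ri,
                                        seed = seeds[ci, ri],
                                        classification = rep_cls$classification)
    }
    n_ok <- length(classes)
    k <- sum(classes %in% c("ring", "ring_like"))
    ci95 <- if (n_ok > 0) stats::binom.test(k, n_ok)$conf.int else c(NA, NA)
    rows[[ci]] <- cbind(param_grid[ci, , drop = FALSE],
                        data.frame(n_ok = n_ok, n_failed = n_failed,
                                   n_ring = sum(classes == "ring"),
                                   n_ring_like = sum(classes == "ring_like"),
                                   p_ring_like = if (n_ok > 0) k / n_ok else NA,
                                   ci_lo = ci95[1], ci_hi = ci95[2]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- do.call(rbind, reps)
  out
}

#' One-sided test that boundary attraction increases ring formation
#'
#' Compares P(ring or ring-like) between the `confine_attract` and
#' `confine_only` arms of a [ring_probability()] table with a one-sided
#' exact test (Fisher) of H0: p_attract <= p_confine.
#'
#' @param tab a [ring_probability()] result containing a `boundary_mode`
#'   column with both arms (a single pair of rows).
#' @return list with `p_value`, `p_attract`, `p_confine` and the 2x2 table.
#' @export
compare_boundary_modes <- function(tab) {
  a <- tab[tab$boundary_mode == "confine_attract", ]
  b <- tab[tab$boundary_mode == "confine_only", ]
  if (nrow(a) != 1 || nrow(b) != 1)
    stop("need exactly one row per boundary mode")
  ka <- a$n_ring + a$n_ring_like
  kb <- b$n_ring + b$n_ring_like
  m <- matrix(c(ka, a$n_ok - ka, kb, b$n_ok - kb), 2, 2, byrow = TRUE,
              dimnames = list(c("attract", "confine"), c("ring", "no_ring")))
  ft <- stats::fisher.test(m, alternative = "greater")
  list(p_value = ft$p.value, p_attract = a$p_ring_like,
       p_confine = b$p_ring_like, table = m)
}

#' Simulated maximum-intensity projection of a filament system
#'
#' Renders each bead as an isotropic Gaussian blob on a 3D grid and projects
#' by taking the maximum (not the sum) along z, emulating how confocal
#' z-stacks of the structures would be displayed.
#'
#' @param sys a [filament_system()].
#' @param voxel_size grid spacing (um).
#' @param psf_sigma Gaussian blob sigma (um).
#' @param pad margin around the bead bounding box (um).
#' @return numeric matrix (rows = y, cols = x) with attributes `voxel_size`
#'   and `origin` (um coordinates of the first pixel centre).
#' @export
simulated_mip <- function(sys, voxel_size = 0.1, psf_sigma = 0.15,
                          pad = 3 * psf_sigma) {
  pos <- sys$positions
  stopifnot(nrow(pos) > 0)
  lo <- apply(pos, 2, min) - pad
  hi <- apply(pos, 2, max) + pad
  nx <- max(2, ceiling((hi[1] - lo[1]) / voxel_size))
  ny <- max(2, ceiling((hi[2] - lo[2]) / voxel_size))
  nz <- max(2, ceiling((hi[3] - lo[3]) / voxel_size))
  xs <- lo[1] + (seq_len(nx) - 0.5) * voxel_size
  ys <- lo[2] + (seq_len(ny) - 0.5) * voxel_size
  zs <- lo[3] + (seq_len(nz) - 0.5) * voxel_size
  vol <- array(0, c(nz, ny, nx))
  wrad <- 3 * psf_sigma
  for (b in seq_len(nrow(pos))) {
    ix <- which(abs(xs - pos[b, 1]) <= wrad)
    iy <- which(abs(ys - pos[b, 2]) <= wrad)
    iz <- which(abs(zs - pos[b, 3]) <= wrad)
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-(xs[ix] - pos[b, 1])^2 / (2 * psf_sigma^2))
    gy <- exp(-(ys[iy] - pos[b, 2])^2 / (2 * psf_sigma^2))
    gz <- exp(-(zs[iz] - pos[b, 3])^2 / (2 * psf_sigma^2))
    blob <- outer(gz, outer(gy, gx))  # (z, y, x)
    vol[iz, iy, ix] <- vol[iz, iy, ix] + blob
  }
  img <- apply(vol, c(2, 3), max)
  attr(img, "voxel_size") <- voxel_size
  attr(img, "origin") <- c(x = unname(lo[1] + 0.5 * voxel_size),
                           y = unname(lo[2] + 0.5 * voxel_size))
  img
}
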