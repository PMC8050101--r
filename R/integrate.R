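#' Advance a filament system by overdamped Brownian dynamics
#'
#' Euler--Maruyama update
#' `x <- x + (F/gamma) dt + sqrt(2 kT dt / gamma) xi` with `xi` standard
#' normal per coordinate, repeated `n_steps` times. Forces are the full
#' deterministic field (springs, bending, cross-links, boundary). A hard
#' radial cap at `R + 0.04 l0` backs up the wall spring so the confinement
#' invariant holds pathwise. Polymerization is off; see [polymerize()] and
#' [run_simulation()] for growth.
#'
#' The integrator owns a counter-based RNG stream seeded by `seed`, so the
#' trajectory is bit-reproducible from `(sys, params, seed)` and independent
#' of R's global RNG state.
#'
#' @param sys a [filament_system()].
#' @param params a [sim_params()].
#' @param n_steps number of timesteps.
#' @param seed integer stream seed; defaults to `params$seed`.
#' @return The advanced `filament_system`. If a coordinate became non-finite
#'   the run aborts with a diagnostic error carrying the last state.
#' @export
bd_step <- function(sys, params, n_steps = 1, seed = params$seed) {
  res <- bd_run_cpp(sys$positions, sys$filament, sys$monomer_pool, sys$time,
                    cpp_par(params), as.integer(n_steps), 0L,
                    as.integer(seed), TRUE, FALSE)
  out <- .sys_from_cpp(res, sys)
  if (isTRUE(res$aborted))
    stop("bd_step: ", res$abort_message, call. = FALSE)
  out
}

#' Grow filaments at their barbed ends
#'
#' Each filament's barbed end gains one bead with probability
#' `polymerization_rate * dt` per step, debiting `subunits_per_bead` from the
#' monomer pool; growth stops when the pool is exhausted. The new bead is
#' placed at distance `l0` along the terminal tangent plus angular noise, and
#' is projected inside the sphere if needed. Bead positions are not moved
#' (pure growth); [run_simulation()] interleaves motion and growth.
#'
#' @inheritParams bd_step
#' @param n_steps number of growth attempts per filament.
#' @return The grown `filament_system`.
#' @export
polymerize <- function(sys, params, n_steps = 1, seed = params$seed) {
  res <- bd_run_cpp(sys$positions, sys$filament, sys$monomer_pool, sys$time,
                    cpp_par(params), as.integer(n_steps), 0L,
                    as.integer(seed), FALSE, TRUE)
  .sys_from_cpp(res, sys)
}

.sys_from_cpp <- function(res, sys) {
  filament_system(res$positions, res$filament,
                  monomer_pool = res$monomer_pool,
                  subunits_per_bead = sys$subunits_per_bead,
                  time = res$time, total_budget = sys$total_budget)
}

#' Run a full simulation
#'
#' Seeds the system from `params` ([init_seeds()]), then loops
#' forces -> Euler--Maruyama step -> polymerization, storing snapshots every
#' `snapshot_interval` seconds. Identical `params` (including `seed`) give a
#' bit-identical trajectory.
#'
#' @param params a [sim_params()].
#' @param sys optional pre-built starting [filament_system()]; by default the
#'   system is seeded from `params`.
#' @param verbose print progress lines to stderr.
#' @return An object of class `trajectory`: list with `params`, `times`,
#'   `snapshots` (each a `filament_system`), and `aborted` flag. If the
#'   integrator hit a non-finite coordinate the partial trajectory is
#'   returned with `aborted = TRUE`.
#' @export
run_simulation <- function(params, sys = NULL, verbose = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(sys)) sys <- init_seeds(params)
  snap_every <- max(1L, as.integer(round(params$snapshot_interval / params$dt)))
  if (verbose)
    message(sprintf("run_simulation: %d beads, %d steps, dt = %.3g s",
                    nrow(sys$positions), params$n_steps, params$dt))
  res <- bd_run_cpp(sys$positions, sys$filament, sys$monomer_pool, sys$time,
                    cpp_par(params), params$n_steps, snap_every,
                    params$seed, TRUE, TRUE)
  snaps <- lapply(res$snapshots, function(s)
    filament_system(s$positions, s$filament, monomer_pool = s$monomer_pool,
                    subunits_per_bead = sys$subunits_per_bead,
                    time = s$time, total_budget = sys$total_budget))
  if (verbose && isTRUE(res$aborted))
    message("run_simulation: aborted: ", res$abort_message)
  structure(list(params = params, times = res$snapshot_times,
                 snapshots = snaps, aborted = isTRUE(res$aborted),
                 abort_message = res$abort_message),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d snapshots over %.4g s%s\n",
              length(x$snapshots), max(x$times),
              if (x$aborted) " [ABORTED]" else ""))
  invisible(x)
}

#' Final snapshot of a trajectory
#' @param traj a `trajectory`.
#' @return the last stored `filament_system`.
#' @export
final_snapshot <- function(traj) traj$snapshots[[length(traj$snapshots)]]

#' @export
as.data.frame.trajectory <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$snapshots), function(i) {
    df <- as.data.frame(x$snapshots[[i]])
    cbind(snapshot = i, time = x$times[i], df)
  }))
}

#' Write / read a trajectory
#'
#' The on-disk container is R native serialization (`.rds`) holding the full
#' parameter set, seed and snapshots -- sufficient to replay the run -- plus
#' an optional flat CSV export with one row per bead
#' (snapshot, time, filament_id, bead_index, x, y, z in um).
#'
#' @param traj a `trajectory`; @param path output file path.
#' @return `path` invisibly ([read_trajectory()] returns the trajectory).
#' @export
write_trajectory <- function(traj, path) {
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) readRDS(path)

#' @rdname write_trajectory
#' @export
export_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
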