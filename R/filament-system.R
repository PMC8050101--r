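#' Construct a filament system from bead positions
#'
#' The state container of the simulator: bead positions (um, origin at the
#' sphere centre) plus filament topology and the unpolymerized monomer pool.
#' Beads belonging to one filament occupy a contiguous block of rows in chain
#' order; the last bead of each block is the barbed (growing) end.
#'
#' @param positions numeric n x 3 matrix of bead coordinates (um).
#' @param filament integer vector, one filament id per bead; ids must label
#'   contiguous blocks.
#' @param monomer_pool unpolymerized subunits remaining.
#' @param subunits_per_bead subunits represented by one bead.
#' @param time simulation time (s).
#' @param total_budget total subunit budget (polymerized + pooled); kept for
#'   conservation checks. Defaults to the current content.
#' @return An object of class `filament_system`.
#' @export
filament_system <- function(positions, filament, monomer_pool = 0,
                            subunits_per_bead = 37, time = 0,
                            total_budget = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  filament <- as.integer(filament)
  if (length(filament) != nrow(positions))
    stop("filament must have one id per bead")
  if (anyDuplicated(rle(filament)$values) > 0)
    stop("beads of one filament must be contiguous")
  if (is.null(total_budget))
    total_budget <- nrow(positions) * subunits_per_bead + monomer_pool
  structure(list(positions = positions, filament = filament,
                 monomer_pool = monomer_pool,
                 subunits_per_bead = subunits_per_bead,
                 time = time, total_budget = total_budget),
            class = "filament_system")
}

#' @export
print.filament_system <- function(x, ...) {
  cat(sprintf(paste0("filament_system: %d beads in %d filaments, pool %.0f",
                     " subunits, t = %.4g s\n"),
              nrow(x$positions), length(unique(x$filament)),
              x$monomer_pool, x$time))
  invisible(x)
}

#' Number of beads per filament
#' @param sys a `filament_system`.
#' @return named integer vector (names = filament ids).
#' @export
filament_sizes <- function(sys) {
  r <- rle(sys$filament)
  stats::setNames(r$lengths, r$values)
}

#' Seed a filament system from concentration and geometry
#'
#' Places `N_seed` two-bead filament seeds uniformly (position and
#' orientation) inside the confining sphere. The seed count realizes the
#' actin concentration: the total subunit budget is `c * N_A * V_sphere` and
#' `N_seed = round(budget / (rho * L))`, so that filaments polymerized to the
#' target length `L` exhaust the pool. `rho = 370` subunits/um is actin's
#' linear subunit density.
#'
#' @param params a [sim_params()] object.
#' @param seed RNG seed for placement; defaults to `params$seed`.
#' @return A [filament_system()] holding the seeds and the remaining monomer
#'   pool.
#' @export
#' @examples
#' sys <- init_seeds(sim_params(R = 2.5, L = 1.2, c = 2, total_time = 0.01))
#' length(unique(sys$filament))  # 178 seeds
init_seeds <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  avogadro_per_um3 <- 602.214076  # subunits per um^3 at 1 uM
  V <- 4 / 3 * pi * params$R^3
  budget <- params$c * avogadro_per_um3 * V
  n_seed <- round(budget / (params$rho * params$L))
  spb <- params$subunits_per_bead
  if (n_seed < 1 || budget < 2 * spb)
    stop(sprintf(paste0("init_seeds: subunit budget %.0f in a sphere of",
                        " radius %g um is too small for a single two-bead",
                        " seed of target length %g um"),
                 budget, params$R, params$L))
  pool <- budget - n_seed * 2 * spb
  if (pool < 0) {
    n_seed <- floor(budget / (2 * spb))
    pool <- budget - n_seed * 2 * spb
  }

  with_seed(seed, function() {
    # uniform positions in the sphere (radius margin keeps both beads inside)
    rmax <- params$R - params$l0 - 1e-6
    u <- stats::runif(n_seed)
    r <- rmax * u^(1 / 3)
    th <- acos(stats::runif(n_seed, -1, 1))
    ph <- stats::runif(n_seed, 0, 2 * pi)
    ctr <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
    # uniform orientations
    om <- acos(stats::runif(n_seed, -1, 1))
    op <- stats::runif(n_seed, 0, 2 * pi)
    dir <- cbind(sin(om) * cos(op), sin(om) * sin(op), cos(om))
    p1 <- ctr - 0.5 * params$l0 * dir
    p2 <- ctr + 0.5 * params$l0 * dir
    pos <- matrix(0, 2 * n_seed, 3)
    pos[seq(1, 2 * n_seed, by = 2), ] <- p1
    pos[seq(2, 2 * n_seed, by = 2), ] <- p2
    filament_system(pos, rep(seq_len(n_seed), each = 2),
                    monomer_pool = pool, subunits_per_bead = spb,
                    time = 0, total_budget = budget)
  })
}

#' Check the state invariants of a filament system
#'
#' Verifies confinement (`|x| <= R + 0.05 l0`), chain topology (contiguous
#' blocks of >= 2 beads), bond lengths within `[0.5, 1.5] l0`, and subunit
#' conservation against the recorded budget.
#'
#' @param sys a `filament_system`; @param params a `sim_params`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_filament_system <- function(sys, params) {
  r <- sqrt(rowSums(sys$positions^2))
  if (any(r > params$R + 0.05 * params$l0 + 1e-9))
    stop("invariant violated: bead outside R + 0.05 * l0")
  sizes <- filament_sizes(sys)
  if (any(sizes < 2)) stop("invariant violated: filament with < 2 beads")
  bonded <- sys$filament[-1] == sys$filament[-length(sys$filament)]
  d <- sqrt(rowSums((sys$positions[-1, , drop = FALSE] -
                     sys$positions[-nrow(sys$positions), , drop = FALSE])^2))
  d <- d[bonded]
  if (any(d < 0.5 * params$l0 | d > 1.5 * params$l0))
    stop("invariant violated: bond length outside [0.5, 1.5] * l0")
  tot <- nrow(sys$positions) * sys$subunits_per_bead + sys$monomer_pool
  if (abs(tot - sys$total_budget) > 1e-6 * max(1, sys$total_budget))
    stop("invariant violated: subunit budget not conserved")
  invisible(TRUE)
}

#' @export
as.data.frame.filament_system <- function(x, ...) {
  idx <- stats::ave(seq_along(x$filament), x$filament, FUN = seq_along)
  data.frame(filament_id = x$filament, bead_index = idx,
             x = x$positions[, 1], y = x$positions[, 2],
             z = x$positions[, 3])
}
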