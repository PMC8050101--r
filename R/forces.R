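#' Deterministic force components and their energies
#'
#' Each function returns an n x 3 matrix of per-bead forces (pN) for one
#' component of the force field; the matching `*_energy()` returns the scalar
#' potential energy (pN um) whose negative gradient the forces are. The
#' pairing is exact (up to the piecewise-linear truncation radii), which is
#' what the finite-difference gradient tests exercise.
#'
#' * `spring_forces()`: Hookean backbone bonds, `-k_spring (|d| - l0) dhat`.
#' * `bending_forces()`: worm-like-chain bending, energy
#'   `kappa (1 - cos theta)` per interior joint with
#'   `kappa = Lp * kT / l0`; the three forces of a triplet sum to zero.
#' * `crosslink_forces()`: cross-filament short-range attraction, a spring
#'   anchored at contact `sigma_c` active below `r_c`, with excluded-volume
#'   repulsion below contact. Pairs on the same filament are excluded.
#' * `boundary_forces()`: radial wall spring outside `R`; in
#'   `confine_attract` mode an additional surface-attraction well on
#'   `(R - d_b, R]`; plus the optional validation trap. Purely radial.
#'
#' @param sys a [filament_system()].
#' @param params a [sim_params()].
#' @return n x 3 force matrix, or a scalar energy.
#' @name forces
NULL

#' @rdname forces
#' @export
spring_forces <- function(sys, params) {
  spring_forces_cpp(sys$positions, sys$filament, params$k_spring, params$l0)
}

#' @rdname forces
#' @export
spring_energy <- function(sys, params) {
  spring_energy_cpp(sys$positions, sys$filament, params$k_spring, params$l0)
}

#' @rdname forces
#' @export
bending_forces <- function(sys, params) {
  bending_forces_cpp(sys$positions, sys$filament, params$kappa_bend)
}

#' @rdname forces
#' @export
bending_energy <- function(sys, params) {
  bending_energy_cpp(sys$positions, sys$filament, params$kappa_bend)
}

#' @rdname forces
#' @export
crosslink_forces <- function(sys, params) {
  crosslink_forces_cpp(sys$positions, sys$filament, cpp_par(params))
}

#' @rdname forces
#' @export
crosslink_energy <- function(sys, params) {
  crosslink_energy_cpp(sys$positions, sys$filament, cpp_par(params))
}

#' @rdname forces
#' @export
boundary_forces <- function(sys, params) {
  boundary_forces_cpp(sys$positions, cpp_par(params))
}

#' @rdname forces
#' @export
boundary_energy <- function(sys, params) {
  boundary_energy_cpp(sys$positions, cpp_par(params))
}

#' @rdname forces
#' @export
total_forces <- function(sys, params) {
  spring_forces(sys, params) + bending_forces(sys, params) +
    crosslink_forces(sys, params) + boundary_forces(sys, params)
}
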