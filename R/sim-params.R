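#' Simulation parameters for confined actin filament dynamics
#'
#' Collects every physical and numerical parameter of a Brownian-dynamics run
#' of polymerizing, cross-linking semiflexible filaments inside a sphere.
#' Units are micrometres (um), piconewtons (pN), pN um (energy) and seconds
#' throughout.
#'
#' The force field is: harmonic backbone springs (stiffness `k_spring`, rest
#' length `l0`); discrete worm-like-chain bending with energy
#' `(Lp * kT / l0) * (1 - cos(theta))` per interior joint; a short-range
#' cross-filament attraction that is a harmonic spring anchored at the contact
#' distance `sigma_c`, active up to `r_c`, with excluded-volume repulsion
#' (stiffness `k_rep`) below contact; a radial hard-wall spring (`k_b`) at the
#' confining radius `R`; and, when `boundary_mode = "confine_attract"`, a
#' harmonic surface-attraction well of stiffness `k_ba` spanning the shell
#' `(R - d_b, R]` -- the model proxy for membrane anchoring.
#'
#' When `dt` is `NULL` it is set to `0.05 * gamma / k_max` where `k_max` is
#' the largest force constant in play (including the effective bending
#' stiffness `kappa / l0^2`), which keeps the overdamped Euler-Maruyama
#' update well inside its stability region. Construction fails if
#' `dt * max(k_spring, k_atr, k_b) / gamma >= 0.1`.
#'
#' @param R confining sphere radius (um).
#' @param L target mean filament length (um); sets the number of seeds.
#' @param c actin concentration (uM); sets the total subunit budget.
#' @param l0 bead spacing / bond rest length (um).
#' @param Lp filament persistence length (um); 17 um is the accepted value
#'   for bare actin.
#' @param lp_stiffen multiplier on `Lp` emulating cross-linking-induced
#'   bundle stiffening (1 = off).
#' @param kT thermal energy (pN um); 4.1e-3 at room temperature.
#' @param gamma bead drag (pN s/um). Default: Stokes drag `6 pi eta (l0/2)`
#'   of an `l0`-sized segment in water-like viscosity (eta = 1e-3 pN s/um^2).
#' @param k_spring backbone spring constant (pN/um).
#' @param k_atr cross-link (bundling) attraction spring constant (pN/um).
#' @param r_c cross-link capture range (um); must be `< R`.
#' @param sigma_c contact distance where attraction hands over to
#'   excluded-volume repulsion (um).
#' @param k_rep excluded-volume repulsion stiffness (pN/um); defaults to
#'   `k_spring`.
#' @param boundary_mode `"confine_only"` (hard wall) or `"confine_attract"`
#'   (hard wall plus surface attraction).
#' @param k_b wall spring constant (pN/um).
#' @param k_ba surface-attraction spring constant (pN/um); the well depth
#'   `k_ba * d_b^2 / 2` (about 27 kT at defaults) makes anchoring effectively
#'   irreversible, as for biotin--neutravidin linkage.
#' @param d_b surface-attraction range (um); must be `< R`.
#' @param polymerization_rate barbed-end bead addition rate (beads/s per
#'   filament) while the monomer pool lasts.
#' @param poly_angle_sd angular noise on the growth direction (dimensionless
#'   sd added to the unit tangent before renormalizing).
#' @param dt timestep (s); `NULL` picks it automatically (see Details).
#' @param total_time simulated duration (s).
#' @param snapshot_interval interval between stored snapshots (s).
#' @param seed integer master seed for the run.
#' @param rho subunits per um of filament; 370 follows from actin's helical
#'   geometry (two strands, 2.7 nm rise per subunit).
#' @param trap_stiffness optional central harmonic trap (pN/um) applied to
#'   every bead; a validation harness for equipartition checks, 0 = off.
#'
#' @return An object of class `sim_params` (a validated named list, with the
#'   derived fields `kappa_bend`, `subunits_per_bead` and `n_steps`).
#' @export
#' @examples
#' p <- sim_params(R = 2.5, L = 1.2, c = 2, total_time = 0.01)
#' p$dt
sim_params <- function(R = 2.5, L = 1.2, c = 2,
                       l0 = 0.1, Lp = 17, lp_stiffen = 1,
                       kT = 4.1e-3, gamma = NULL,
                       k_spring = 100, k_atr = 2, r_c = 0.15, sigma_c = 0.1,
                       k_rep = NULL,
                       boundary_mode = c("confine_only", "confine_attract"),
                       k_b = 100, k_ba = 10, d_b = 0.15,
                       polymerization_rate = 25, poly_angle_sd = 0.2,
                       dt = NULL, total_time = 0.5, snapshot_interval = 0.1,
                       seed = 1L, rho = 370, trap_stiffness = 0) {
  boundary_mode <- match.arg(boundary_mode)
  if (is.null(gamma)) gamma <- 6 * pi * 1e-3 * (l0 / 2)
  if (is.null(k_rep)) k_rep <- k_spring

  pos <- c(R = R, L = L, c = c, l0 = l0, Lp = Lp, lp_stiffen = lp_stiffen,
           kT = kT, gamma = gamma, k_spring = k_spring, k_atr = k_atr,
           r_c = r_c, sigma_c = sigma_c, k_rep = k_rep, k_b = k_b,
           k_ba = k_ba, d_b = d_b,
           polymerization_rate = polymerization_rate,
           total_time = total_time, snapshot_interval = snapshot_interval,
           rho = rho)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad) > 0)
    stop("sim_params: fields must be strictly positive and finite: ",
         paste(bad, collapse = ", "))
  if (trap_stiffness < 0) stop("sim_params: trap_stiffness must be >= 0")
  if (r_c < sigma_c) stop("sim_params: r_c must be >= sigma_c")
  if (r_c >= R) stop("sim_params: r_c must be smaller than R")
  if (d_b >= R) stop("sim_params: d_b must be smaller than R")
  if (l0 > L) stop("sim_params: bead spacing l0 cannot exceed target length L")

  kappa_bend <- Lp * lp_stiffen * kT / l0
  k_max <- max(k_spring, k_atr, k_rep, k_b, k_ba, kappa_bend / l0^2,
               trap_stiffness)
  if (is.null(dt)) dt <- 0.05 * gamma / k_max
  if (!is.finite(dt) || dt <= 0) stop("sim_params: dt must be positive")
  stab <- dt * max(k_spring, k_atr, k_b) / gamma
  if (stab >= 0.1)
    stop(sprintf(paste0("sim_params: unstable timestep: dt * max(k_spring,",
                        " k_atr, k_b) / gamma = %.3g >= 0.1"), stab))

  p <- list(R = R, L = L, c = c, l0 = l0, Lp = Lp, lp_stiffen = lp_stiffen,
            kT = kT, gamma = gamma, k_spring = k_spring, k_atr = k_atr,
            r_c = r_c, sigma_c = sigma_c, k_rep = k_rep,
            boundary_mode = boundary_mode, k_b = k_b, k_ba = k_ba, d_b = d_b,
            polymerization_rate = polymerization_rate,
            poly_angle_sd = poly_angle_sd,
            dt = dt, total_time = total_time,
            snapshot_interval = snapshot_interval,
            seed = as.integer(seed), rho = rho,
            trap_stiffness = trap_stiffness,
            kappa_bend = kappa_bend,
            subunits_per_bead = max(1, round(rho * l0)),
            n_steps = max(1L, as.integer(round(total_time / dt))))
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Brownian-dynamics parameters (um, pN, s)\n")
  cat(sprintf("  sphere R = %g um, target L = %g um, c = %g uM\n",
              x$R, x$L, x$c))
  cat(sprintf("  l0 = %g, Lp = %g (x%g), kT = %g, gamma = %.3g\n",
              x$l0, x$Lp, x$lp_stiffen, x$kT, x$gamma))
  cat(sprintf("  k_spring = %g, k_atr = %g on [%g, %g], boundary %s (k_b = %g, k_ba = %g, d_b = %g)\n",
              x$k_spring, x$k_atr, x$sigma_c, x$r_c, x$boundary_mode,
              x$k_b, x$k_ba, x$d_b))
  cat(sprintf("  dt = %.3g s, total = %g s (%d steps), seed = %d\n",
              x$dt, x$total_time, x$n_steps, x$seed))
  invisible(x)
}

# parameter list handed to the C++ kernels
cpp_par <- function(params, trap_k = NULL) {
  list(R = params$R, l0 = params$l0, kT = params$kT, gamma = params$gamma,
       k_spring = params$k_spring, kappa_bend = params$kappa_bend,
       k_atr = params$k_atr, r_c = params$r_c, sigma_c = params$sigma_c,
       k_rep = params$k_rep,
       attract = identical(params$boundary_mode, "confine_attract"),
       k_b = params$k_b, k_ba = params$k_ba, d_b = params$d_b,
       trap_k = if (is.null(trap_k)) params$trap_stiffness else trap_k,
       dt = params$dt, poly_rate = params$polymerization_rate,
       poly_angle_sd = params$poly_angle_sd,
       spb = params$subunits_per_bead)
}

# run fn with a private RNG stream; global .Random.seed is restored on exit
with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fn()
}
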