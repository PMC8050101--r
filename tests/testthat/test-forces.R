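# The force field: analytic forces must be exact negative gradients of the
# declared energies, obey Newton's third law, and vanish where the
# potentials are flat.

test_that("rest configurations feel no force", {
  p <- free_params()
  # bond at rest length
  sys <- straight_filament(2, l0 = p$l0)
  expect_equal(max(abs(spring_forces(sys, p))), 0)
  # collinear triplet: bending minimum
  sys3 <- straight_filament(3, l0 = p$l0)
  expect_equal(max(abs(bending_forces(sys3, p))), 0)
  # cross-filament pair beyond the capture range
  far <- combine_systems(straight_filament(2, l0 = p$l0),
                         straight_filament(2, l0 = p$l0,
                                           origin = c(0, 2 * p$r_c, 0)))
  expect_equal(max(abs(crosslink_forces(far, p))), 0)
  # bead at the sphere centre, both boundary modes
  ctr <- filament_system(matrix(c(0, 0, 0, 0.1, 0, 0), 2, 3, byrow = TRUE),
                         c(1L, 1L))
  expect_equal(max(abs(boundary_forces(ctr, p))), 0)
  pa <- free_params(boundary_mode = "confine_attract")
  expect_equal(max(abs(boundary_forces(ctr, pa))), 0)
})

test_that("a stretched bond follows Hooke's law", {
  p <- free_params()
  delta <- 0.013
  sys <- filament_system(rbind(c(0, 0, 0), c(p$l0 + delta, 0, 0)),
                         c(1L, 1L))
  f <- spring_forces(sys, p)
  expect_equal(f[1, ], c(p$k_spring * delta, 0, 0), tolerance = 1e-12)
  expect_equal(f[2, ], -f[1, ], tolerance = 1e-12)
})

test_that("the wall spring pushes straight back in", {
  p <- free_params(R = 2.5)
  eps <- 0.01
  sys <- filament_system(rbind(c(2.5 + eps, 0, 0), c(2.4, 0, 0)),
                         c(1L, 1L))
  f <- boundary_forces(sys, p)
  expect_equal(f[1, ], c(-p$k_b * eps, 0, 0), tolerance = 1e-10)
  expect_equal(f[2, ], c(0, 0, 0))
})

test_that("forces match finite-difference gradients to 1e-6", {
  p <- free_params(boundary_mode = "confine_attract", R = 1.2)
  for (seed in c(3, 11, 29)) {
    pos <- random_chain(10, seed)
    sys <- filament_system(pos, rep(1L, 10))
    expect_lt(force_gradient_error(spring_forces, spring_energy, sys, p),
              1e-6)
    expect_lt(force_gradient_error(bending_forces, bending_energy, sys, p),
              1e-6)
    # two nearby filaments with pair separations inside (sigma_c, r_c)
    pos2 <- rbind(pos, sweep(pos, 2, c(0.5 * (p$sigma_c + p$r_c), 0.02,
                                       -0.01), "+"))
    sys2 <- filament_system(pos2, rep(1:2, each = 10))
    expect_lt(force_gradient_error(crosslink_forces, crosslink_energy,
                                   sys2, p), 1e-6)
    # beads straddling the attraction shell and the wall
    set.seed(seed)
    rr <- runif(8, p$R - p$d_b + 0.01, p$R + 0.02)
    dirs <- matrix(rnorm(24), 8, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    sysb <- filament_system(rr * dirs, rep(1:4, each = 2))
    expect_lt(force_gradient_error(boundary_forces, boundary_energy,
                                   sysb, p), 1e-6)
  }
})

test_that("internal forces obey Newton's third law system-wide", {
  p <- free_params()
  pos <- rbind(random_chain(8, 5), random_chain(8, 6, origin = c(0.1, 0, 0)))
  sys <- filament_system(pos, rep(1:2, each = 8))
  for (ffun in list(spring_forces, bending_forces, crosslink_forces)) {
    f <- ffun(sys, p)
    expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-10)
  }
})

test_that("the cross-link attraction defaults to 2 pN/um", {
  expect_equal(sim_params()$k_atr, 2)
})

test_that("surface attraction pulls outward inside the shell", {
  p <- free_params(boundary_mode = "confine_attract", R = 2.5)
  r0 <- p$R - p$d_b / 2
  sys <- filament_system(rbind(c(r0, 0, 0), c(r0 - 0.05, 0, 0)),
                         c(1L, 1L))
  f <- boundary_forces(sys, p)
  expect_gt(f[1, 1], 0)  # outward
  expect_equal(f[1, 1], p$k_ba * (p$R - r0), tolerance = 1e-10)
})
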