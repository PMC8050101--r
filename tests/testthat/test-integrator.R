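# Stochastic physics of the Euler-Maruyama integrator, checked against
# closed forms at fixed seeds.

test_that("identical seeds give identical trajectories", {
  p <- free_params()
  sys <- combine_systems(straight_filament(5, l0 = p$l0),
                         straight_filament(5, l0 = p$l0,
                                           origin = c(0, 0.5, 0)))
  a <- bd_step(sys, p, n_steps = 500, seed = 42)
  b <- bd_step(sys, p, n_steps = 500, seed = 42)
  expect_identical(a$positions, b$positions)
  c1 <- bd_step(sys, p, n_steps = 500, seed = 43)
  expect_false(identical(a$positions, c1$positions))
})

test_that("zero temperature and zero force freeze the system", {
  p <- free_params(kT = 1e-12)
  p$kT <- 0  # construction requires > 0; the integrator honours 0 exactly
  sys <- straight_filament(5, l0 = p$l0)
  out <- bd_step(sys, p, n_steps = 200, seed = 1)
  expect_equal(out$positions, sys$positions, tolerance = 1e-12)
  expect_equal(out$time, sys$time + 200 * p$dt)
})

test_that("free beads diffuse with D = kT / gamma", {
  p <- free_params(k_atr = 1e-9)
  # 300 independent two-bead filaments scattered far apart: bonded pairs
  # diffuse freely as dumbbells; use centre-of-mass MSD with D_cm = D / 2
  set.seed(9)
  m <- 600
  base <- rbind(c(0, 0, 0), c(p$l0, 0, 0))
  offs <- matrix(runif(3 * m, -200, 200), m, 3)
  pos <- do.call(rbind, lapply(seq_len(m), function(i)
    sweep(base, 2, offs[i, ], "+")))
  sys <- filament_system(pos, rep(seq_len(m), each = 2))
  n_steps <- 10000
  out <- bd_step(sys, p, n_steps = n_steps, seed = 77)
  t_el <- n_steps * p$dt
  com0 <- (pos[seq(1, 2 * m, 2), ] + pos[seq(2, 2 * m, 2), ]) / 2
  com1 <- (out$positions[seq(1, 2 * m, 2), ] +
           out$positions[seq(2, 2 * m, 2), ]) / 2
  msd <- mean(rowSums((com1 - com0)^2))
  expected <- 6 * (p$kT / (2 * p$gamma)) * t_el
  expect_equal(msd / expected, 1, tolerance = 0.05)
})

test_that("a harmonic trap equilibrates to kT / k variance per axis", {
  k_trap <- 1
  p <- free_params(trap_stiffness = k_trap, k_atr = 1e-9,
                   k_rep = 1e-9)
  set.seed(4)
  m <- 200
  pos <- do.call(rbind, lapply(seq_len(m), function(i)
    rbind(c(0, 0, 0), c(p$l0, 0, 0))))
  sys <- filament_system(pos, rep(seq_len(m), each = 2))
  # burn in, then sample repeatedly
  sys <- bd_step(sys, p, n_steps = 40000, seed = 10)
  xs <- NULL
  for (rep in 1:20) {
    sys <- bd_step(sys, p, n_steps = 1500, seed = 100 + rep)
    com <- (sys$positions[seq(1, 2 * m, 2), ] +
            sys$positions[seq(2, 2 * m, 2), ]) / 2
    xs <- rbind(xs, com)
  }
  # dumbbell centre of mass: stiffness 2 k_trap, drag 2 gamma -> var kT/(2k)
  v <- mean(apply(xs, 2, stats::var))
  expect_equal(v / (p$kT / (2 * k_trap)), 1, tolerance = 0.05)
})

test_that("bond lengths equilibrate at the rest length", {
  p <- free_params()
  set.seed(5)
  m <- 100
  pos <- do.call(rbind, lapply(seq_len(m), function(i)
    sweep(rbind(c(0, 0, 0), c(p$l0, 0, 0)), 2, runif(3, -50, 50), "+")))
  sys <- filament_system(pos, rep(seq_len(m), each = 2))
  sys <- bd_step(sys, p, n_steps = 3000, seed = 20)
  bl <- NULL
  for (rep in 1:15) {
    sys <- bd_step(sys, p, n_steps = 600, seed = 200 + rep)
    d <- sys$positions[seq(2, 2 * m, 2), ] - sys$positions[seq(1, 2 * m, 2), ]
    bl <- c(bl, sqrt(rowSums(d^2)))
  }
  expect_equal(mean(bl) / p$l0, 1, tolerance = 0.05)
})

test_that("two parallel filaments zip to contact like the reduced ODE", {
  # kT = 0: each bead pair evolves as d' = -(2 k_atr / gamma)(d - sigma_c),
  # closed form d(t) = sigma_c + (d0 - sigma_c) exp(-2 k_atr t / gamma).
  # Bead spacing 2 r_c keeps diagonal pairs out of range, so the per-pair
  # reduction is exact.
  p <- free_params(l0 = 0.3)
  p$kT <- 0
  d0 <- 0.8 * p$r_c
  a <- straight_filament(5, l0 = p$l0)
  b <- straight_filament(5, l0 = p$l0, origin = c(0, d0, 0))
  sys <- combine_systems(a, b)
  n_steps <- 2000
  out <- bd_step(sys, p, n_steps = n_steps, seed = 1)
  t_el <- n_steps * p$dt
  d_pred <- p$sigma_c + (d0 - p$sigma_c) * exp(-2 * p$k_atr * t_el / p$gamma)
  gaps <- out$positions[6:10, 2] - out$positions[1:5, 2]
  expect_equal(mean(gaps) / d_pred, 1, tolerance = 0.01)
})

test_that("divergent dynamics abort with a diagnostic", {
  p <- free_params()
  p$dt <- 10      # bypass construction: deliberately unstable
  p$R <- Inf      # no confinement cap to arrest the blow-up
  sys <- straight_filament(6, l0 = 2 * p$l0)  # stretched: huge forces
  expect_error(bd_step(sys, p, n_steps = 5000, seed = 1), "non-finite")
})

test_that("beads never escape the confinement cap", {
  p <- sim_params(R = 1.5, L = 0.6, c = 2, total_time = 5e-4,
                  snapshot_interval = 1e-4, seed = 3)
  tr <- run_simulation(p)
  for (s in tr$snapshots)
    expect_true(all(sqrt(rowSums(s$positions^2)) <=
                      p$R + 0.05 * p$l0 + 1e-12))
})
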