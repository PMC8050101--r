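# Full-loop behaviour: growth, conservation, reproducibility, and the
# worm-like-chain statistics of the discrete bending model.

test_that("a full run is reproducible and conserves subunits", {
  p <- sim_params(R = 1.5, L = 0.6, c = 2, total_time = 2e-3,
                  snapshot_interval = 5e-4, polymerization_rate = 2000,
                  seed = 11)
  tr1 <- run_simulation(p)
  tr2 <- run_simulation(p)
  expect_identical(final_snapshot(tr1)$positions,
                   final_snapshot(tr2)$positions)
  expect_false(tr1$aborted)
  expect_true(all(diff(tr1$times) > 0))
  budget <- final_snapshot(tr1)$total_budget
  for (s in tr1$snapshots) {
    expect_equal(nrow(s$positions) * s$subunits_per_bead + s$monomer_pool,
                 budget, tolerance = 1e-9)
    expect_silent(validate_filament_system(s, p))
  }
  # growth happened
  expect_gt(nrow(final_snapshot(tr1)$positions),
            nrow(tr1$snapshots[[1]]$positions))
})

test_that("trajectories round-trip through disk and CSV", {
  p <- sim_params(R = 1.5, L = 0.6, c = 1, total_time = 1e-3,
                  snapshot_interval = 5e-4, seed = 2)
  tr <- run_simulation(p)
  tmp <- tempfile(fileext = ".rds")
  write_trajectory(tr, tmp)
  tr2 <- read_trajectory(tmp)
  expect_identical(final_snapshot(tr)$positions,
                   final_snapshot(tr2)$positions)
  csv <- tempfile(fileext = ".csv")
  export_trajectory_csv(tr, csv)
  df <- read.csv(csv)
  expect_named(df, c("snapshot", "time", "filament_id", "bead_index",
                     "x", "y", "z"))
  expect_equal(nrow(df), sum(vapply(tr$snapshots,
                                    function(s) nrow(s$positions),
                                    numeric(1))))
  unlink(c(tmp, csv))
})

test_that("dynamics preserve the worm-like-chain tangent correlation", {
  # Free filaments started from the exact discrete-WLC Boltzmann
  # distribution (joint angles ~ exp(kappa~ cos th) sin th). The integrator
  # must hold <t(0).t(s)> = exp(-s / Lp); wrong bending forces or noise
  # amplitudes would relax the local modes to a different correlation
  # within the sampled window.
  sample_wlc <- function(nb, l0, kap) {
    tv <- matrix(0, nb - 1, 3)
    tv[1, ] <- { u <- rnorm(3); u / sqrt(sum(u^2)) }
    for (k in 2:(nb - 1)) {
      U <- runif(1)
      cth <- 1 + log(U + (1 - U) * exp(-2 * kap)) / kap
      sth <- sqrt(max(0, 1 - cth^2))
      phi <- runif(1, 0, 2 * pi)
      t0 <- tv[k - 1, ]
      a <- if (abs(t0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a - sum(a * t0) * t0; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(t0[2] * e1[3] - t0[3] * e1[2],
              t0[3] * e1[1] - t0[1] * e1[3],
              t0[1] * e1[2] - t0[2] * e1[1])
      tv[k, ] <- cth * t0 + sth * (cos(phi) * e1 + sin(phi) * e2)
    }
    rbind(c(0, 0, 0), apply(tv * l0, 2, cumsum))
  }
  for (Lp in c(1, 10, 17)) {
    p0 <- free_params(L = 4, l0 = 0.1, Lp = Lp, k_atr = 1e-9)
    # finer timestep than the production default: the Euler-Maruyama
    # variance inflation at dt*k/gamma = 0.05 visibly broadens the
    # large-angle bend distribution of the floppiest chains
    p <- free_params(L = 4, l0 = 0.1, Lp = Lp, k_atr = 1e-9,
                     dt = 0.4 * p0$dt)
    nb <- 41
    m <- 100
    kap <- Lp / p$l0
    set.seed(Lp)
    pos <- do.call(rbind, lapply(seq_len(m), function(i)
      sweep(sample_wlc(nb, p$l0, kap), 2, runif(3, -200, 200), "+")))
    sys <- filament_system(pos, rep(seq_len(m), each = nb))
    sys <- bd_step(sys, p, n_steps = 40000, seed = Lp)
    lags <- 1:8
    acc <- matrix(0, 0, length(lags))
    for (rep in 1:6) {
      sys <- bd_step(sys, p, n_steps = 6000, seed = 1000 * Lp + rep)
      for (f in seq_len(m)) {
        pp <- sys$positions[((f - 1) * nb + 1):(f * nb), ]
        tv <- diff(pp)
        tv <- tv / sqrt(rowSums(tv^2))
        cors <- vapply(lags, function(k)
          mean(rowSums(tv[1:(nb - 1 - k), , drop = FALSE] *
                       tv[(1 + k):(nb - 1), , drop = FALSE])),
          numeric(1))
        acc <- rbind(acc, cors)
      }
    }
    cbar <- colMeans(acc)
    fit <- stats::lm(log(cbar) ~ 0 + I(lags * p$l0))
    Lp_hat <- -1 / stats::coef(fit)[[1]]
    expect_equal(Lp_hat, Lp, tolerance = 0.15)
  }
})
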