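test_that("an empty scene renders to zeros", {
  g <- make_geometry(scene_spec("ring", R_ves = 6, seed = 1))
  g$curves <- list()
  g$truth$class <- "none"
  st <- render_stack(g, render_spec(gain = 0, read_noise_sd = 0,
                                    lognormal_sd = 0), seed = 1,
                     membrane = FALSE)
  expect_equal(max(st$actin), 0)
})

test_that("deposited intensity is proportional to curve length", {
  rs <- render_spec(psf_sigma_xy = 0, psf_sigma_z = 0, gain = 0,
                    read_noise_sd = 0, lognormal_sd = 0)
  for (kind in c("ring", "straight_chords")) {
    g <- make_geometry(scene_spec(kind, R_ves = 6, seed = 3))
    st <- render_stack(g, rs, seed = 3, membrane = FALSE)
    total_len <- sum(vapply(g$curves, function(cv)
      sum(sqrt(rowSums(diff(cv)^2))), numeric(1)))
    expect_equal(sum(st$actin), total_len, tolerance = 0.01)
  }
})

test_that("rendering is deterministic in the seed", {
  sp <- scene_spec("cortex_arcs", R_ves = 6, n_arcs = 4, seed = 5)
  a <- render_stack(sp, render_spec(), seed = 9)
  b <- render_stack(sp, render_spec(), seed = 9)
  expect_identical(a$actin, b$actin)
  c1 <- render_stack(sp, render_spec(), seed = 10)
  expect_false(identical(a$actin, c1$actin))
})

test_that("noise statistics follow the Poisson plus read-noise model", {
  gain <- 30
  rn <- 0.05
  rs <- render_spec(gain = gain, read_noise_sd = rn, lognormal_sd = 0)
  # bright scene: at the tested voxels the clamp at zero is negligible, so
  # the unclipped Poisson + read-noise variance applies
  sp <- scene_spec("ring", R_ves = 6, intensity = 20, seed = 4)
  reps <- lapply(1:60, function(k) render_stack(sp, rs, seed = 100 + k,
                                                membrane = FALSE)$actin)
  arr <- simplify2array(reps)
  mu <- apply(arr, 1:3, mean)
  vv <- apply(arr, 1:3, stats::var)
  sel <- mu > 0.5 * max(mu)
  # clipping at zero is negligible for bright voxels
  pred <- mu[sel] / gain + rn^2
  expect_equal(mean(vv[sel] / pred), 1, tolerance = 0.1)
})

test_that("per-vesicle brightness is log-normal across seeds", {
  rs <- render_spec(gain = 0, read_noise_sd = 0, lognormal_mu = 0,
                    lognormal_sd = 0.4)
  sp <- scene_spec("ring", R_ves = 6, seed = 4)
  br <- vapply(1:40, function(k)
    render_stack(sp, rs, seed = k, membrane = FALSE)$metadata$brightness,
    numeric(1))
  expect_equal(sd(log(br)), 0.4, tolerance = 0.35)
  expect_equal(mean(log(br)), 0, tolerance = 0.2)
})

test_that("stacks round-trip through TIFF and JSON", {
  sp <- scene_spec("ring_with_gap", R_ves = 6, seed = 7)
  st <- render_stack(sp, render_spec(gain = 0, read_noise_sd = 0,
                                     lognormal_sd = 0), seed = 7)
  base <- file.path(tempdir(), "rt")
  write_stack(st, base)
  st2 <- read_stack(base)
  expect_equal(dim(st2$actin), dim(st$actin))
  expect_equal(st2$actin, st$actin, tolerance = 1e-6)
  expect_equal(st2$z_spacing, st$z_spacing)
  expect_equal(st2$metadata$truth$class, "ring_like")
  expect_false(is.null(st2$membrane))
  unlink(paste0(base, c("_actin.tif", "_membrane.tif", "_meta.json")))
})

test_that("the fixture suite writes a consistent catalog", {
  out <- file.path(tempdir(), "fixtures")
  cat1 <- fixture_suite(out, R_ves = 6, seed = 2)
  expect_true(all(c("membrane_shell", "center_blob", "uniform_fill",
                    "ring") %in% cat1$kind))
  expect_equal(nrow(cat1),
               length(list.files(out, pattern = "_actin.tif$")))
  expect_true(file.exists(file.path(out, "catalog.csv")))
  # metadata round-trips through the reader
  st <- read_stack(file.path(out, "membrane_shell"))
  expect_equal(st$metadata$kind, "membrane_shell")
  expect_equal(st$metadata$truth$radial, 1)
  unlink(out, recursive = TRUE)
})
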