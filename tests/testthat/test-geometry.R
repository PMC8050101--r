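test_that("generated curves have their declared geometry", {
  for (seed in c(1, 9, 33)) {
    g <- make_geometry(scene_spec("ring", R_ves = 8, seed = seed))
    cv <- g$curves[[1]]
    expect_equal(max(abs(sqrt(rowSums(cv^2)) - 8)), 0, tolerance = 1e-9)
    expect_lt(sum((cv[1, ] - cv[nrow(cv), ])^2), 0.01)  # closed
    expect_equal(g$truth$class, "ring")
    expect_equal(g$truth$kappa_rel, 1)

    ch <- make_geometry(scene_spec("straight_chords", R_ves = 8,
                                   seed = seed))
    for (cc in ch$curves) {
      d <- sweep(cc, 2, cc[1, ])
      u <- d[nrow(d), ] / sqrt(sum(d[nrow(d), ]^2))
      resid <- d - (d %*% u) %*% t(u)
      expect_lt(max(abs(resid)), 1e-9)  # perfectly straight
      expect_true(all(sqrt(rowSums(cc^2)) <= 8))
    }
    expect_equal(ch$truth$kappa_rel, 0)

    co <- make_geometry(scene_spec("cortex_arcs", R_ves = 8, n_arcs = 8,
                                   seed = seed))
    expect_length(co$curves, 8)
    for (cc in co$curves)
      expect_lt(max(abs(sqrt(rowSums(cc^2)) - 8)), 1e-9)
  }
})

test_that("the gapped ring honours its gap fraction", {
  g <- make_geometry(scene_spec("ring_with_gap", gap_fraction = 0.05,
                                R_ves = 8, seed = 2))
  cv <- g$curves[[1]]
  arc <- sum(sqrt(rowSums(diff(cv)^2)))
  expect_equal(arc / (2 * pi * 8), 0.95, tolerance = 0.01)
  expect_equal(g$truth$class, "ring_like")
  g2 <- make_geometry(scene_spec("ring_with_gap", gap_fraction = 0.25,
                                 R_ves = 8, seed = 2))
  expect_equal(g2$truth$class, "none")
})

test_that("infeasible scenes are rejected", {
  expect_error(scene_spec("ring", R_ves = -1), "positive")
  expect_error(scene_spec("ring_with_gap", gap_fraction = 1), "gap_fraction")
  expect_error(scene_spec("center_blob", blob_radius = 9, R_ves = 8),
               "blob_radius")
  # too many chords to separate inside a small vesicle
  expect_error(make_geometry(scene_spec("straight_chords", n_chords = 60,
                                        R_ves = 4, seed = 1)),
               "separated chords")
})

test_that("volumetric kinds carry their radial anchors", {
  expect_equal(make_geometry(scene_spec("membrane_shell"))$truth$radial, 1)
  expect_equal(make_geometry(scene_spec("center_blob"))$truth$radial, 0)
  expect_length(make_geometry(scene_spec("uniform_fill"))$curves, 0)
})
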