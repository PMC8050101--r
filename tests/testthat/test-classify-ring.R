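# The topology classifier against a brute-force cycle oracle and on the
# canonical morphologies.

test_that("classification matches expectations on the fixture set", {
  fx <- fixture_graphs()
  expect_gte(length(fx), 12)
  for (nm in names(fx)) {
    r <- classify_ring(fx[[nm]]$g)
    expect_equal(r$classification, fx[[nm]]$class, label = nm)
    expect_true(r$cycle_fraction >= 0 && r$cycle_fraction <= 1)
    expect_true(r$gap_fraction >= 0 && r$gap_fraction <= 1)
  }
})

test_that("largest-cycle weight agrees with brute-force enumeration", {
  fx <- fixture_graphs()
  for (nm in names(fx)) {
    g <- fx[[nm]]$g
    if (nrow(g$edges) > 16) next
    r <- classify_ring(g, branch_min = 0)  # no spur pruning: raw topology
    expect_equal(r$details$largest_cycle, oracle_max_cycle(g),
                 tolerance = 1e-9, label = nm)
    expect_false(r$details$cycle_search_capped)
  }
})

test_that("classification is invariant under rigid motion and relabeling", {
  fx <- fixture_graphs()
  set.seed(99)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  rot <- Rx %*% Rz
  for (nm in c("closed_ring", "gap5", "ring_plus_branch", "theta_graph")) {
    g <- fx[[nm]]$g
    base <- classify_ring(g)
    moved <- bundle_graph(sweep(g$nodes %*% rot, 2, c(7, -3, 1), "+"),
                          g$edges$from, g$edges$to, g$bundling_distance)
    r2 <- classify_ring(moved)
    expect_equal(r2$classification, base$classification, label = nm)
    expect_equal(r2$cycle_fraction, base$cycle_fraction, tolerance = 1e-9)
    # node relabeling
    perm <- sample(nrow(g$nodes))
    inv <- order(perm)
    shuffled <- bundle_graph(g$nodes[perm, , drop = FALSE],
                             inv[g$edges$from], inv[g$edges$to],
                             g$bundling_distance)
    expect_equal(classify_ring(shuffled)$classification,
                 base$classification, label = paste(nm, "permuted"))
  }
})

test_that("thresholds are honoured and reported", {
  g <- circle_graph(16, gap = 0.05)
  strict <- classify_ring(g, g_max = 0.04)
  expect_equal(strict$classification, "none")
  lax <- classify_ring(g, g_max = 0.1)
  expect_equal(lax$classification, "ring_like")
  expect_equal(lax$details$g_max, 0.1)
  r <- classify_ring(circle_graph(16), f_min = 0.8)
  expect_equal(r$details$f_min, 0.8)
  expect_equal(r$details$total_contour, r$details$largest_cycle,
               tolerance = 1e-9)
})
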