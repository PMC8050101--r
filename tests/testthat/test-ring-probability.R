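# Sweep bookkeeping with stubbed classifiers (fast, tiny simulations).

tiny_grid <- data.frame(boundary_mode = c("confine_only",
                                          "confine_attract"),
                        stringsAsFactors = FALSE)
tiny_base <- list(R = 1.2, L = 0.4, c = 1, l0 = 0.1, total_time = 2e-4,
                  snapshot_interval = 1e-4, polymerization_rate = 100)

test_that("a classifier that never fires gives probability zero", {
  stub <- function(graph) list(classification = "none")
  tab <- ring_probability(tiny_grid, n_replicates = 3, master_seed = 5,
                          classify_fun = stub, base_args = tiny_base)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$p_ring_like, c(0, 0))
  expect_equal(tab$n_ok, c(3, 3))
  expect_true(all(tab$ci_lo == 0))
})

test_that("probabilities reproduce a fixed label sequence", {
  # stub replays 7 ring / 3 none labels per condition
  labels <- rep(c("ring", "none"), c(7, 3))
  i <- 0
  stub <- function(graph) {
    i <<- i + 1
    list(classification = labels[(i - 1) %% 10 + 1])
  }
  tab <- ring_probability(tiny_grid[1, , drop = FALSE], n_replicates = 10,
                          master_seed = 1, classify_fun = stub,
                          base_args = tiny_base)
  expect_equal(tab$p_ring_like, 0.7)
  expect_equal(tab$n_ring, 7)
  # Clopper-Pearson CI brackets the point estimate
  expect_lt(tab$ci_lo, 0.7)
  expect_gt(tab$ci_hi, 0.7)
  binom <- stats::binom.test(7, 10)$conf.int
  expect_equal(c(tab$ci_lo, tab$ci_hi), as.numeric(binom),
               tolerance = 1e-9)
})

test_that("replicate metadata is recorded and seeds are reproducible", {
  stub <- function(graph) list(classification = "none")
  t1 <- ring_probability(tiny_grid, 2, master_seed = 9,
                         classify_fun = stub, base_args = tiny_base)
  t2 <- ring_probability(tiny_grid, 2, master_seed = 9,
                         classify_fun = stub, base_args = tiny_base)
  r1 <- attr(t1, "replicates")
  r2 <- attr(t2, "replicates")
  expect_equal(r1$seed, r2$seed)
  expect_equal(nrow(r1), 4)
  t3 <- ring_probability(tiny_grid, 2, master_seed = 10,
                         classify_fun = stub, base_args = tiny_base)
  expect_false(all(attr(t3, "replicates")$seed == r1$seed))
})

test_that("the attraction comparison runs a one-sided exact test", {
  tab <- data.frame(boundary_mode = c("confine_attract", "confine_only"),
                    n_ok = c(20, 20), n_ring = c(9, 1),
                    n_ring_like = c(3, 1),
                    p_ring_like = c(0.6, 0.1))
  cmp <- compare_boundary_modes(tab)
  expect_lt(cmp$p_value, 0.05)
  expect_equal(cmp$p_attract, 0.6)
  # reversing the counts cannot reject
  tab2 <- tab
  tab2$n_ring <- rev(tab$n_ring)
  tab2$n_ring_like <- rev(tab$n_ring_like)
  expect_gt(compare_boundary_modes(tab2)$p_value, 0.5)
})
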