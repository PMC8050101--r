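# End-to-end topology recovery: rendered geometry -> skeleton -> bundle
# graph -> ring classification, against the generator's ground truth.

clean_render <- function(kind, seed, R_ves = 8, ...)
  render_stack(scene_spec(kind, R_ves = R_ves, seed = seed, ...),
               render_spec(gain = 0, read_noise_sd = 0, lognormal_sd = 0),
               seed = seed)

test_that("canonical morphologies classify to their ground truth", {
  cases <- list(list("ring", "ring"),
                list("ring_with_gap", "ring_like"),
                list("ring_with_branch", "ring_like"),
                list("cortex_arcs", "none"),
                list("straight_chords", "none"))
  for (cs in cases) {
    st <- clean_render(cs[[1]], seed = 13)
    geo <- detect_vesicle(st)
    r <- classify_ring_image(extract_skeleton(st, geo), geo)
    expect_equal(r$classification, cs[[2]], label = cs[[1]])
  }
})

test_that("classification is perfect across seeds on unambiguous scenes", {
  cases <- list(ring = c(101, 102, 103, 104, 105, 106, 107),
                cortex_arcs = c(201, 202, 203, 204, 205, 206, 207),
                straight_chords = c(301, 302, 303, 304, 305, 306))
  expected <- c(ring = "ring", cortex_arcs = "none",
                straight_chords = "none")
  n_correct <- 0; n_total <- 0
  for (kind in names(cases)) {
    for (sd1 in cases[[kind]]) {
      st <- clean_render(kind, seed = sd1)
      geo <- detect_vesicle(st)
      r <- classify_ring_image(extract_skeleton(st, geo), geo)
      n_total <- n_total + 1
      if (r$classification == expected[kind]) n_correct <- n_correct + 1
      expect_equal(r$classification, unname(expected[kind]),
                   label = sprintf("%s seed %d", kind, sd1))
    }
  }
  expect_equal(n_correct, n_total)
})

test_that("agreement between image and graph routes on the same scene", {
  # classifying the noiseless analytic curves must agree with classifying
  # the rendered and re-extracted version
  g <- make_geometry(scene_spec("ring_with_gap", R_ves = 8, seed = 21))
  cv <- g$curves[[1]]
  n <- nrow(cv)
  keep <- seq(1, n, by = 6)
  graph <- bundle_graph(cv[keep, ], seq_len(length(keep) - 1),
                        seq_len(length(keep) - 1) + 1, 0.15)
  direct <- classify_ring(graph)
  st <- render_stack(g, render_spec(gain = 0, read_noise_sd = 0,
                                    lognormal_sd = 0), seed = 21)
  geo <- detect_vesicle(st)
  imaged <- classify_ring_image(extract_skeleton(st, geo), geo)
  expect_equal(imaged$classification, direct$classification)
})
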