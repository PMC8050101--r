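test_that("a single bead projects to one Gaussian spot", {
  sys <- filament_system(rbind(c(0, 0, 0), c(0.1, 0, 0)), c(1L, 1L))
  img <- simulated_mip(sys, voxel_size = 0.05, psf_sigma = 0.15)
  expect_true(all(img >= 0))
  # the two beads are 0.1 um apart in x; peak near their midline
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  org <- attr(img, "origin")
  vx <- attr(img, "voxel_size")
  x_pk <- org["x"] + (pk[2] - 1) * vx
  y_pk <- org["y"] + (pk[1] - 1) * vx
  expect_lt(abs(x_pk - 0.05), 0.06)
  expect_lt(abs(y_pk - 0), 0.06)
})

test_that("beads stacked in z combine by maximum, not sum", {
  far <- 2  # several sigma apart in z: blobs do not overlap
  sys1 <- filament_system(rbind(c(0, 0, 0), c(0, 0, far)), c(1L, 1L))
  img2 <- simulated_mip(sys1, voxel_size = 0.05, psf_sigma = 0.15)
  single <- filament_system(rbind(c(0, 0, 0), c(0, 0, 0.05)), c(1L, 1L))
  img1 <- simulated_mip(single, voxel_size = 0.05, psf_sigma = 0.15)
  # peak of the stacked pair equals one blob's peak, not twice it
  expect_lt(max(img2), 1.2)
  expect_gt(max(img2), 0.8)
})

test_that("a ring projects onto the analytic circle", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  r0 <- 2
  pos <- cbind(r0 * cos(th), r0 * sin(th), 0.3 * sin(3 * th))
  sys <- filament_system(pos, rep(1L, 100))
  vx <- 0.1
  sigma <- 0.15
  img <- simulated_mip(sys, voxel_size = vx, psf_sigma = sigma)
  org <- attr(img, "origin")
  # oracle: dense per-pixel evaluation of max-over-z of the blob field
  bright <- which(img > 0.5 * max(img), arr.ind = TRUE)
  xs <- org["x"] + (bright[, 2] - 1) * vx
  ys <- org["y"] + (bright[, 1] - 1) * vx
  rad <- sqrt(xs^2 + ys^2)
  expect_true(all(abs(rad - r0) < 3 * sigma))
  # direct evaluation at a probe row of pixels matches the rendered image
  iy <- nrow(img) %/% 2
  y0 <- org["y"] + (iy - 1) * vx
  probe <- vapply(seq_len(ncol(img)), function(ix) {
    x0 <- org["x"] + (ix - 1) * vx
    # max over z evaluated on a fine z grid of the summed blob field
    zg <- seq(-1, 1, by = 0.02)
    vals <- vapply(zg, function(z)
      sum(exp(-((x0 - pos[, 1])^2 + (y0 - pos[, 2])^2 +
                  (z - pos[, 3])^2) / (2 * sigma^2))), numeric(1))
    max(vals)
  }, numeric(1))
  # rendered max-over-z uses the coarse voxel z grid: allow discretization
  expect_lt(max(abs(img[iy, ] - probe)) / max(probe), 0.08)
})
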