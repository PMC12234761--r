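test_that("isosurface of the analytic sphere is sub-half-voxel accurate", {
  vol <- sphere_volume(0.5)
  mesh <- extract_isosurface(vol, 0)
  err <- sqrt(rowSums(mesh$vertices^2)) - 10
  expect_lt(sqrt(mean(err^2)), 0.25)
  # convergence: at least first-order in voxel size
  vol2 <- sphere_volume(0.25)
  mesh2 <- extract_isosurface(vol2, 0)
  err2 <- sqrt(rowSums(mesh2$vertices^2)) - 10
  expect_lt(sqrt(mean(err2^2)) / sqrt(mean(err^2)), 0.5 * 1.25)
})

test_that("degenerate thresholds raise empty-surface errors", {
  const <- scan_volume(array(7, c(4, 4, 4)), rep(1, 3), value_range = c(0, 10))
  expect_error(extract_isosurface(const, 7), "no surface")
  vol <- sphere_volume(1)
  expect_error(extract_isosurface(vol, 100), "no surface")
})

test_that("axis-aligned slab recovers two sheets at half-voxel accuracy", {
  h <- 0.4
  g <- seq(-8, 8, by = h)
  line <- ifelse(abs(g) < 3, 1, 0)
  vol <- scan_volume(array(rep(line, each = 49), c(7, 7, length(g))),
                     rep(h, 3), origin = c(0, 0, -8))
  mesh <- extract_isosurface(vol, 0.5)
  interior <- mesh$vertices[, 1] > h & mesh$vertices[, 1] < 6 * h &
              mesh$vertices[, 2] > h & mesh$vertices[, 2] < 6 * h
  z <- mesh$vertices[interior, 3]
  expect_true(all(abs(abs(z) - 3) < h / 2 + 1e-9))
  expect_gt(sum(z > 0), 0)
  expect_gt(sum(z < 0), 0)
})

test_that("surface separates voxels above and below the threshold", {
  vol <- sphere_volume(1, R = 5, pad = 2)
  mesh <- extract_isosurface(vol, 0)
  d <- dim(vol$values)
  set.seed(9)
  n_checked <- 0
  while (n_checked < 100) {
    ijk_in <- cbind(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    ijk_out <- cbind(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
    v_in <- vol$values[ijk_in]
    v_out <- vol$values[ijk_out]
    # clearly inside / clearly outside; endpoints jittered off the lattice so
    # the segment cannot thread exactly through mesh vertices or edges
    if (v_in > 0.5 && v_out < -0.5) {
      p0 <- as.numeric(voxel_position(vol, ijk_in)) + runif(3, -0.01, 0.01)
      p1 <- as.numeric(voxel_position(vol, ijk_out)) + runif(3, -0.01, 0.01)
      expect_equal(segment_crossings(mesh, p0, p1) %% 2, 1)
      n_checked <- n_checked + 1
    }
  }
})

test_that("raising the threshold on a blurred slab moves sheets inward", {
  h <- 0.4
  g <- seq(-8, 8, by = h)
  line <- ifelse(abs(g) < 3, 1000, 0)
  vals <- array(rep(line, each = 49), c(7, 7, length(g)))
  blurred <- surfaccuracy:::cpp_gaussian_blur(as.numeric(vals), 7, 7,
                                              length(g), c(0, 0, 2))
  vol <- scan_volume(array(blurred, c(7, 7, length(g))), rep(h, 3),
                     origin = c(0, 0, -8))
  tops <- vapply(c(200, 350, 500, 650, 800), function(t) {
    m <- extract_isosurface(vol, t)
    mean(m$vertices[m$vertices[, 3] > 0, 3])
  }, numeric(1))
  expect_true(all(diff(tops) < 0))
  # symmetric blur: the midpoint threshold recovers the true sheet position
  m500 <- extract_isosurface(vol, 500)
  expect_equal(mean(m500$vertices[m500$vertices[, 3] > 0, 3]), 3,
               tolerance = 1e-6)
})

test_that("threshold suggestion lands between the modes", {
  two_delta <- scan_volume(array(rep(c(100, 900), each = 100), c(10, 10, 2)),
                           rep(1, 3))
  t1 <- suggest_threshold(two_delta)
  expect_gt(t1, 450)
  expect_lt(t1, 550)

  set.seed(12)
  mix <- c(rnorm(4000, 0, 50), rnorm(2000, 1200, 50))
  bimodal <- scan_volume(array(mix, c(30, 20, 10)), rep(1, 3))
  t2 <- suggest_threshold(bimodal)
  expect_gt(t2, 200)
  expect_lt(t2, 1000)

  const <- scan_volume(array(5, c(4, 4, 4)), rep(1, 3), value_range = c(0, 10))
  expect_warning(t3 <- suggest_threshold(const), "constant")
  expect_equal(t3, 5)
})
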