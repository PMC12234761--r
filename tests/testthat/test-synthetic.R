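test_that("phantom generation is deterministic, closed and bilateral", {
  a <- make_phantom(phantom_spec(seed = 5), n_rings = 20, n_around = 64)
  b <- make_phantom(phantom_spec(seed = 5), n_rings = 20, n_around = 64)
  expect_identical(a$mesh, b$mesh)
  c2 <- make_phantom(phantom_spec(seed = 6), n_rings = 20, n_around = 64)
  expect_false(identical(a$mesh$vertices, c2$mesh$vertices))

  # closed manifold: every edge shared by exactly two consistently wound faces
  f <- a$mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2))
  expect_false(any(duplicated(paste(e[, 1], e[, 2]))))
  expect_gt(surfaccuracy:::signed_volume(a$mesh), 0)

  expect_length(a$measurement, 8)
  seeds <- t(sapply(a$measurement, `[[`, "seed"))
  expect_equal(seeds[c(1, 3, 5, 7), 1], -seeds[c(2, 4, 6, 8), 1])
  expect_equal(seeds[c(1, 3, 5, 7), 2:3], seeds[c(2, 4, 6, 8), 2:3])
  # seeds lie on the surface
  expect_lt(max(closest_point(a$mesh, seeds)$distance), 0.05)
})

test_that("voxelization recovers the truth within half a voxel", {
  ph <- test_phantom()
  acq <- acquisition_spec(c(0.4, 0.4, 0.4), psf_sigma_mm = 0, noise_sd_ref = 0)
  vol <- voxelize(ph$mesh, acq)
  mesh <- extract_isosurface(vol, 600)
  d <- closest_point(ph$mesh, mesh$vertices)$distance
  expect_lt(sqrt(mean(d^2)), 0.2)

  # half-voxel grid offset: recovery error still within half a voxel
  acq_off <- acquisition_spec(c(0.4, 0.4, 0.4), psf_sigma_mm = 0,
                              noise_sd_ref = 0,
                              grid_offset_frac = c(0.5, 0.5, 0.5))
  mesh_off <- extract_isosurface(voxelize(ph$mesh, acq_off), 600)
  d_off <- closest_point(ph$mesh, mesh_off$vertices)$distance
  expect_lt(sqrt(mean(d_off^2)), 0.2)
})

test_that("noise and exposure scaling behave as specified", {
  ph <- test_phantom()
  acq0 <- acquisition_spec(c(0.5, 0.5, 0.5), psf_sigma_mm = 0.3,
                           noise_sd_ref = 0, seed = 3)
  v1 <- voxelize(ph$mesh, acq0)
  v2 <- voxelize(ph$mesh, acq0)
  expect_identical(v1$values, v2$values)  # sd = 0 path is deterministic

  acq1 <- acquisition_spec(c(0.5, 0.5, 0.5), psf_sigma_mm = 0.3,
                           noise_sd_ref = 60, exposure_ref_s = 12,
                           exposure_s = 12, seed = 3)
  expect_equal(acquisition_noise_sd(acq1), 60)
  acq2 <- acquisition_spec(c(0.5, 0.5, 0.5), psf_sigma_mm = 0.3,
                           noise_sd_ref = 60, exposure_ref_s = 12,
                           exposure_s = 6, seed = 3)
  expect_equal(acquisition_noise_sd(acq2), 60 * sqrt(2))

  vn <- voxelize(ph$mesh, acq1)
  noise <- vn$values - v1$values
  expect_equal(sd(noise), 60, tolerance = 0.02)
  # same seed reproduces the same noise
  expect_identical(vn$values, voxelize(ph$mesh, acq1)$values)
})

test_that("zero threshold jitter yields identical repeats, jitter separates them", {
  ph <- test_phantom()
  acq <- acquisition_preset("cbct_0.3", noise = 0, seed = 2)
  sess0 <- simulate_session(ph$mesh, acq, operator_spec(jitter_sd = 0), 2)
  expect_equal(sess0$thresholds[1], sess0$thresholds[2])
  m1 <- extract_isosurface(sess0$volume, sess0$thresholds[1])
  m2 <- extract_isosurface(sess0$volume, sess0$thresholds[2])
  expect_identical(m1, m2)
  expect_equal(mad_sdad(distance_field(m1, m2))$mad, 0)

  sess <- simulate_session(ph$mesh, acq, operator_spec(jitter_sd = 40, seed = 8), 2)
  expect_false(sess$thresholds[1] == sess$thresholds[2])
  ma <- extract_isosurface(sess$volume, sess$thresholds[1])
  mb <- extract_isosurface(sess$volume, sess$thresholds[2])
  expect_gt(mad_sdad(distance_field(ma, mb))$mad, 0)
})

test_that("acquisition presets carry the study's voxel sizes and doses", {
  ct <- acquisition_preset("ct")
  expect_equal(ct$voxel_mm[3], 0.625)
  expect_true(ct$voxel_mm[1] < ct$voxel_mm[3])  # anisotropic slices
  expect_equal(acquisition_preset("cbct_0.3")$voxel_mm, rep(0.3, 3))
  f <- acquisition_preset("cbct_0.2")
  u <- acquisition_preset("cbct_0.2_lowdose")
  expect_equal(f$voxel_mm, rep(0.2, 3))
  expect_equal(u$voxel_mm, rep(0.2, 3))
  expect_equal(u$exposure_s, f$exposure_s / 2)
  expect_equal(acquisition_noise_sd(u), sqrt(2) * acquisition_noise_sd(f))
})
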