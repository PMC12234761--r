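test_that("patch growth is seeded, sized and deterministic", {
  plane <- plane_grid(30, spacing = 0.5)
  seed <- c(7.6, 7.6, 0)
  p1 <- grow_patch(plane, region_spec(seed, size = 1))
  expect_length(p1$faces, 1)
  hit <- closest_point(plane, seed)
  expect_equal(p1$faces, hit$face)

  spec <- region_spec(seed, size = 200, label = "disc")
  pa <- grow_patch(plane, spec)
  pb <- grow_patch(plane, spec)
  expect_identical(pa$faces, pb$faces)
  expect_length(pa$faces, 200)

  # disc-like: all patch faces within r + one ring of the seed
  areas <- face_areas(plane)
  r_disc <- sqrt(sum(areas[pa$faces]) / pi)
  cent <- (plane$vertices[plane$faces[, 1], ] + plane$vertices[plane$faces[, 2], ] +
           plane$vertices[plane$faces[, 3], ]) / 3
  d <- sqrt(rowSums(sweep(cent[pa$faces, ], 2, seed)^2))
  expect_lt(max(d), r_disc + 2 * 0.5)
})

test_that("patches larger than the mesh truncate with a warning", {
  cube <- cube_mesh()
  expect_warning(p <- grow_patch(cube, region_spec(c(0, 0, 0), size = 50)),
                 "truncat")
  expect_length(p$faces, 12)
  expect_true(p$truncated)
})

test_that("distance fields match analytic cases", {
  plane <- plane_grid(10)
  offset <- plane_grid(10, z = 0.1)
  expect_equal(distance_field(plane, plane)$distance, rep(0, 121))
  f <- distance_field(offset, plane)
  expect_equal(f$distance, rep(0.1, 121))
  expect_equal(f$signed, rep(0.1, 121))

  s1 <- icosphere(3, radius = 10)
  s2 <- icosphere(3, radius = 10.05)
  f12 <- distance_field(s2, s1)
  r <- mad_sdad(f12)
  expect_equal(r$mad, 0.05, tolerance = 0.01)
})

test_that("MAD/SDAD match hand computations and pooling rules", {
  fake_field <- function(d, region = "r1") {
    structure(data.frame(vertex = seq_along(d), distance = d, signed = d,
                         region = region),
              class = c("distance_field", "data.frame"))
  }
  r0 <- mad_sdad(fake_field(c(0, 0, 0)))
  expect_identical(r0$mad, 0)
  expect_identical(r0$sdad, 0)

  r1 <- mad_sdad(fake_field(c(0.1, 0.1, 0.1)))
  expect_equal(r1$mad, 0.1)
  expect_equal(r1$sdad, 0)

  r2 <- mad_sdad(fake_field(c(0, 0.2)))
  expect_equal(r2$mad, 0.1)
  expect_equal(r2$sdad, 0.1)  # population denominator

  # pooled MAD is the vertex-weighted mean of per-region MADs
  f <- fake_field(c(0.1, 0.2, 0.3, 0.4, 0.6), c("a", "a", "a", "b", "b"))
  r3 <- mad_sdad(f)
  per <- r3$per_region
  expect_equal(r3$mad, sum(per$mad * per$n) / sum(per$n))
  expect_equal(per$mad[per$region == "a"], 0.2)
  expect_equal(per$mad[per$region == "b"], 0.5)
})

test_that("the metric is directional on a coarse-vs-fine pair", {
  coarse <- icosphere(1, radius = 10)
  fine <- icosphere(3, radius = 10)
  m_cf <- mad_sdad(distance_field(coarse, fine))$mad
  m_fc <- mad_sdad(distance_field(fine, coarse))$mad
  expect_false(isTRUE(all.equal(m_cf, m_fc)))
  # fine vertices sit farther from the coarse chordal surface than vice versa
  expect_gt(m_fc, m_cf)
})

test_that("rigidly moved copies measure zero after perfect registration", {
  ph <- test_phantom()
  tr <- compose_motion(list(rx = 3, ry = -2, rz = 1, tx = 1, ty = 0.5, tz = -0.2))
  moved <- transform_mesh(ph$mesh, tr)
  back <- transform_mesh(moved, invert_transform(tr))
  expect_lt(mad_sdad(distance_field(back, ph$mesh))$mad, 1e-6)
})

test_that("distance maps export and read back identically", {
  sph <- icosphere(2)
  patches <- grow_patches(sph, list(region_spec(c(0, 0, 1.1), 40, "cap"),
                                    region_spec(c(0, 0, -1.1), 40, "base")))
  f <- distance_field(sph, icosphere(2, radius = 1.01), regions = patches)
  path <- withr::local_tempfile(fileext = ".ply")
  out <- export_distance_map(f, sph, path, scale_limit = 0.04)
  back <- read_distance_map(path)
  expect_equal(back$mesh$faces, sph$faces)
  scal <- rep(0, nrow(sph$vertices))
  scal[f$vertex] <- f$distance
  expect_equal(back$scalar, scal)
  csv <- utils::read.csv(out$csv, comment.char = "#")
  expect_equal(csv$distance, f$distance)
  # zero field exports all-zero scalars
  f0 <- distance_field(sph, sph, regions = patches)
  p0 <- withr::local_tempfile(fileext = ".ply")
  export_distance_map(f0, sph, p0)
  expect_true(all(read_distance_map(p0)$scalar == 0))
  expect_error(distance_field(sph, sph, regions = list()), "empty region")
})
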