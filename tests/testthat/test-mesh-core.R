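test_that("mesh invariants are enforced", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_s3_class(tri_mesh(v, rbind(c(1, 2, 3))), "tri_mesh")
  expect_error(tri_mesh(v, rbind(c(1, 2, 4))), "out of vertex range")
  expect_error(tri_mesh(v, rbind(c(1, 2, 2))), "repeated vertex")
  expect_error(tri_mesh(rbind(v, c(2, 0, 0)), rbind(c(1, 2, 4))), "area")
  expect_error(tri_mesh(v[0, ], matrix(integer(0), 0, 3)), "empty")
})

test_that("face and vertex normals match analytic expectations", {
  plane <- plane_grid(5)
  expect_equal(face_normals(plane), matrix(rep(c(0, 0, 1), each = 50), 50, 3))
  expect_equal(vertex_normals(plane), matrix(rep(c(0, 0, 1), each = 36), 36, 3))

  # cube corners see three orthogonal faces symmetrically when each quad is
  # fanned around its centre, so corner normals are (+-1, +-1, +-1)/sqrt(3)
  cube <- cube_mesh()
  centers <- do.call(rbind, lapply(seq(1, 12, by = 2), function(i) {
    quad <- unique(as.vector(cube$faces[c(i, i + 1), ]))
    colMeans(cube$vertices[quad, ])
  }))
  v14 <- rbind(cube$vertices, centers)
  f4 <- do.call(rbind, lapply(seq_len(12), function(i) {
    tri <- cube$faces[i, ]
    cidx <- 8 + ceiling(i / 2)
    rbind(c(tri[1], tri[2], cidx), c(tri[2], tri[3], cidx),
          c(tri[3], tri[1], cidx))
  }))
  split_cube <- weld_vertices(tri_mesh(v14, f4, check = FALSE))
  vn_all <- vertex_normals(split_cube)
  corner <- rowSums(split_cube$vertices %% 1 == 0) == 3
  vn <- vn_all[corner, , drop = FALSE]
  expect_equal(abs(vn), matrix(1 / sqrt(3), sum(corner), 3), tolerance = 1e-12)
  # corner normals point away from the centre
  outward <- sign(sweep(split_cube$vertices[corner, , drop = FALSE], 2,
                        c(0.5, 0.5, 0.5)))
  expect_equal(sign(vn), outward)

  # sphere: vertex normals within 2 degrees of radial
  sph <- icosphere(3)
  vn <- vertex_normals(sph)
  radial <- sph$vertices / sqrt(rowSums(sph$vertices^2))
  ang <- acos(pmin(1, rowSums(vn * radial))) * 180 / pi
  expect_lt(max(ang), 2)
})

test_that("closest_point returns the exact surface minimum", {
  sph <- icosphere(2)
  # query offset from a face centroid along its normal
  fc <- (sph$vertices[sph$faces[, 1], ] + sph$vertices[sph$faces[, 2], ] +
         sph$vertices[sph$faces[, 3], ]) / 3
  fn <- face_normals(sph)
  h <- 0.3
  q <- fc[10, ] + h * fn[10, ]
  hit <- closest_point(sph, q)
  expect_equal(hit$distance, h, tolerance = 1e-12)
  expect_equal(as.numeric(hit$point), as.numeric(fc[10, ]), tolerance = 1e-9)

  # distance equals |query - returned point| always
  set.seed(5)
  qs <- matrix(runif(60, -1.5, 1.5), 20, 3)
  hits <- closest_point(sph, qs)
  expect_equal(hits$distance, sqrt(rowSums((qs - hits$point)^2)),
               tolerance = 1e-12)

  # barycentric reconstruction of the surface point
  recon <- sapply(seq_len(20), function(i) {
    fv <- sph$vertices[sph$faces[hits$face[i], ], ]
    as.numeric(hits$bary[i, ] %*% fv)
  })
  expect_equal(t(recon), hits$point, tolerance = 1e-9)

  # edge-region queries agree with the brute-force per-triangle oracle
  for (i in seq_len(20)) {
    oracle <- brute_closest(sph, qs[i, ])
    expect_equal(hits$distance[i], oracle$distance, tolerance = 1e-9)
  }
})

test_that("sphere mesh inradius limit holds at the origin", {
  sph <- icosphere(4)  # 2562 vertices
  expect_equal(nrow(sph$vertices), 2562)
  hit <- closest_point(sph, c(0, 0, 0))
  expect_lt(abs(hit$distance - 1), 0.005)
})

test_that("welding merges duplicated STL-style vertices", {
  cube <- cube_mesh()
  exploded <- tri_mesh(cube$vertices[t(cube$faces), ],
                       matrix(seq_len(36), 12, 3, byrow = TRUE))
  expect_equal(nrow(exploded$vertices), 36)
  welded <- weld_vertices(exploded)
  expect_equal(nrow(welded$vertices), 8)
  expect_equal(nrow(welded$faces), 12)
  expect_equal(sum(face_areas(welded)), 6, tolerance = 1e-12)
})

test_that("transform_mesh applies R p + t", {
  cube <- cube_mesh()
  tr <- compose_motion(list(rx = 10, ry = -5, rz = 20, tx = 1, ty = 2, tz = 3))
  moved <- transform_mesh(cube, tr)
  expect_equal(moved$vertices[1, ],
               as.numeric(tr$rotation %*% cube$vertices[1, ]) + tr$translation)
  back <- transform_mesh(moved, invert_transform(tr))
  expect_equal(back$vertices, cube$vertices, tolerance = 1e-12)
})
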