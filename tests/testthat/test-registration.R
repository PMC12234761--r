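test_that("identical meshes register to the identity with zero objective", {
  ph <- test_phantom()
  reg <- icp_register(ph$mesh, ph$mesh)
  expect_equal(reg$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(reg$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(reg$trace[1], 0)
  expect_true(reg$converged)
})

test_that("a known rigid perturbation is recovered to 0.01 mm / 0.01 degree", {
  ph <- test_phantom()
  injected <- list(rx = 2, ry = -1, rz = 3, tx = 0.5, ty = -0.3, tz = 0.8)
  tr <- compose_motion(injected)
  moved <- transform_mesh(ph$mesh, tr)
  reg <- icp_register(moved, ph$mesh)
  residual <- compose_transform(reg$transform, tr)  # should be identity
  d <- unlist(decompose_transform(residual))
  expect_lt(max(abs(d)), 0.01)
  # post-registration MAD on noiseless meshes is essentially zero
  back <- transform_mesh(moved, reg$transform)
  fld <- distance_field(back, ph$mesh)
  expect_lt(mad_sdad(fld)$mad, 1e-3)
})

test_that("objective trace is monotonically non-increasing", {
  ph <- test_phantom()
  set.seed(21)
  for (i in 1:3) {
    tr <- compose_motion(random_motion(8, 2))
    reg <- icp_register(transform_mesh(ph$mesh, tr), ph$mesh)
    prev <- reg$trace[-length(reg$trace)]
    expect_true(all(diff(reg$trace) <= 1e-12 + 1e-8 * prev))
  }
})

test_that("registration is invariant to a common rigid transform", {
  ph <- test_phantom()
  tr <- compose_motion(list(rx = 1.5, ry = 0.5, rz = -2, tx = 0.4, ty = 0.1, tz = -0.6))
  moved <- transform_mesh(ph$mesh, tr)
  rel1 <- icp_register(moved, ph$mesh)$transform

  common <- compose_motion(list(rx = 12, ry = -7, rz = 25, tx = 10, ty = -4, tz = 6))
  rel2 <- icp_register(transform_mesh(moved, common),
                       transform_mesh(ph$mesh, common))$transform
  # conjugate back into the original frame
  rel2_back <- compose_transform(invert_transform(common),
                                 compose_transform(rel2, common))
  expect_equal(rel1$rotation, rel2_back$rotation, tolerance = 1e-6)
  expect_equal(rel1$translation, rel2_back$translation, tolerance = 1e-6)
})

test_that("linearized step solves the quadratic subproblem", {
  # aligned correspondences give a zero increment
  set.seed(31)
  p <- matrix(runif(60, -5, 5), 20, 3)
  n <- matrix(rnorm(60), 20, 3)
  n <- n / sqrt(rowSums(n^2))
  step <- linearized_point_to_plane_step(p, p, n)
  expect_equal(step$rotation, diag(3), tolerance = 1e-12)
  expect_equal(step$translation, c(0, 0, 0), tolerance = 1e-12)

  # pure translation along z with planar normals
  q <- p
  q[, 3] <- q[, 3] + 0.25
  nz <- matrix(rep(c(0, 0, 1), each = 20), 20, 3)
  step <- linearized_point_to_plane_step(p, q, nz)
  expect_equal(step$translation[3], 0.25, tolerance = 1e-9)

  # random small perturbation: increment matches an independent quadratic solve
  q2 <- p + matrix(rnorm(60, sd = 0.01), 20, 3)
  step2 <- linearized_point_to_plane_step(p, q2, n)
  obj <- function(x) {
    res <- rowSums((p + cbind(x[2] * p[, 3] - x[3] * p[, 2],
                              x[3] * p[, 1] - x[1] * p[, 3],
                              x[1] * p[, 2] - x[2] * p[, 1]) +
                    matrix(x[4:6], 20, 3, byrow = TRUE) - q2) * n)
    sum(res^2)
  }
  fit <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  w <- fit$par[1:3]
  expect_equal(surfaccuracy:::axis_angle_rotation(w), step2$rotation,
               tolerance = 1e-6)
  expect_equal(fit$par[4:6], step2$translation, tolerance = 1e-6)

  # planar normals leave rotation and in-plane translation unconstrained
  expect_equal(attr(step, "rank"), 3)
  expect_equal(step$translation, c(0, 0, 0.25), tolerance = 1e-9)
  expect_equal(step$rotation, diag(3), tolerance = 1e-12)
})

test_that("coplanar reference areas raise a rank-deficiency error", {
  flat <- plane_grid(8)
  expect_error(icp_register(flat, plane_grid(8, z = 0.05)),
               "rank-deficient")
})

test_that("overlap trimming and seeded sampling behave deterministically", {
  ph <- test_phantom()
  tr <- compose_motion(list(rx = 1, ry = 0.5, rz = -1, tx = 0.3, ty = 0.2, tz = -0.1))
  moved <- transform_mesh(ph$mesh, tr)
  s1 <- icp_settings(overlap = 0.8, sampling = 0.5, seed = 7)
  r1 <- icp_register(moved, ph$mesh, settings = s1)
  r2 <- icp_register(moved, ph$mesh, settings = s1)
  expect_identical(r1$transform, r2$transform)
  res <- compose_transform(r1$transform, tr)
  expect_lt(max(abs(unlist(decompose_transform(res)))), 0.01)
})

test_that("decomposition round-trips and handles its edge cases", {
  expect_equal(unlist(decompose_transform(rigid_transform())),
               c(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0))
  rot5 <- compose_motion(list(rx = 5, ry = 0, rz = 0, tx = 0, ty = 0, tz = 0))
  expect_equal(unlist(decompose_transform(rot5)),
               c(tx = 0, ty = 0, tz = 0, rx = 5, ry = 0, rz = 0),
               tolerance = 1e-12)
  gimbal <- compose_motion(list(rx = 0, ry = 90, rz = 0, tx = 0, ty = 0, tz = 0))
  expect_error(decompose_transform(gimbal), "gimbal.*quaternion")

  set.seed(41)
  for (i in 1:200) {
    m <- random_motion(30, 5)
    tr <- compose_motion(m)
    back <- compose_motion(decompose_transform(tr))
    expect_equal(back$rotation, tr$rotation, tolerance = 1e-9)
    expect_equal(back$translation, tr$translation, tolerance = 1e-9)
  }
})
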