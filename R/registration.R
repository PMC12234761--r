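#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 rotation matrix; must be orthonormal with
#'   determinant +1 within `tol`.
#' @param translation length-3 translation vector (mm).
#' @param tol orthonormality tolerance.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > tol || det(rotation) < 0)
    stop("`rotation` is not a proper rotation (orthonormal, det +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  m <- transform_matrix(x)
  print(round(m, 6))
  d <- decompose_transform(x)
  cat(sprintf("  translations (mm): tx %.4g ty %.4g tz %.4g\n", d$tx, d$ty, d$tz))
  cat(sprintf("  rotations (deg):   rx %.4g ry %.4g rz %.4g\n", d$rx, d$ry, d$rz))
  invisible(x)
}

#' 4 x 4 homogeneous matrix of a rigid transform
#' @param transform a [rigid_transform()].
#' @return 4 x 4 numeric matrix.
#' @export
transform_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` returns the transform applying `b` first, then
#' `a` (matrix convention `a %*% b`).
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Decompose a rigid transform into six axis-wise motions
#'
#' Expresses a best-fit motion as three translations (mm) and three rotations
#' (degrees) about the coordinate axes, using the extrinsic X-then-Y-then-Z
#' Euler convention (`R = Rz(rz) Ry(ry) Rx(rx)`), in the fixed mesh's frame.
#' Axis semantics follow the craniofacial convention used throughout the
#' package: X lateral, Y vertical, Z anteroposterior, so `tx` is lateral
#' movement and `rx` rotation about the lateral axis.
#'
#' @param transform a [rigid_transform()].
#' @return list with `tx`, `ty`, `tz` (mm) and `rx`, `ry`, `rz` (degrees),
#'   class `motion_decomposition`.
#' @export
decompose_transform <- function(transform) {
  R <- transform$rotation
  sy <- -R[3, 1]
  if (abs(abs(sy) - 1) < 1e-6) {
    q <- rotation_to_quaternion(R)
    stop(sprintf(
      paste0("gimbal lock: |ry| within 1e-6 of 90 degrees; ",
             "quaternion (w, x, y, z) = (%.9g, %.9g, %.9g, %.9g)"),
      q[1], q[2], q[3], q[4]))
  }
  ry <- asin(sy)
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  structure(list(tx = transform$translation[1],
                 ty = transform$translation[2],
                 tz = transform$translation[3],
                 rx = rx * 180 / pi, ry = ry * 180 / pi, rz = rz * 180 / pi),
            class = "motion_decomposition")
}

#' Rebuild a rigid transform from six axis-wise motions
#'
#' Inverse of [decompose_transform()]: angles in degrees, extrinsic XYZ order.
#'
#' @param motion list with `tx`, `ty`, `tz` (mm), `rx`, `ry`, `rz` (degrees).
#' @return a [rigid_transform()].
#' @export
compose_motion <- function(motion) {
  d <- pi / 180
  R <- rot_z(motion$rz * d) %*% rot_y(motion$ry * d) %*% rot_x(motion$rx * d)
  rigid_transform(R, c(motion$tx, motion$ty, motion$tz))
}

rotation_to_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
      (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1
    k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
    q
  }
}

#' ICP settings
#'
#' Defaults reproduce the registration protocol used for surface-model
#' superimposition: 100% estimated overlap, point-to-plane matching, exact
#' nearest-neighbour search, 100% point sampling, 50 iterations.
#'
#' @param overlap fraction in (0, 1]: each iteration keeps the best
#'   `overlap` fraction of correspondences by distance (trimmed ICP).
#' @param sampling fraction in (0, 1] of reference vertices used, drawn once
#'   by a seeded uniform subsample.
#' @param iterations maximum iterations (>= 1).
#' @param tolerance early stop when the relative objective change falls
#'   below this (default far below numerical noise, so the full iteration
#'   budget is normally spent).
#' @param seed integer seed for the sampling subsample.
#' @return list of class `icp_settings`.
#' @export
icp_settings <- function(overlap = 1, sampling = 1, iterations = 50,
                         tolerance = 1e-10, seed = 1L) {
  stopifnot(overlap > 0, overlap <= 1, sampling > 0, sampling <= 1,
            iterations >= 1)
  structure(list(overlap = overlap, sampling = sampling,
                 iterations = as.integer(iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "icp_settings")
}

#' One linearized point-to-plane update
#'
#' Solves the small-angle linearization of the point-to-plane objective
#' `sum(((R p + t - q) . n)^2)` as a 6 x 6 least-squares system in
#' `(omega, t)` and re-orthonormalizes the incremental rotation through the
#' exact axis-angle exponential.
#'
#' @param p n x 3 moving points.
#' @param q n x 3 target surface points (closest points on the fixed mesh).
#' @param n n x 3 unit normals of the fixed surface at `q`.
#' @return an incremental [rigid_transform()], with attribute `rank` (the
#'   numerical rank of the 6-column linear system; 6 when the constraint
#'   geometry is non-degenerate). Rank-deficient systems get the
#'   minimum-norm solution (so purely planar normals yield a pure
#'   translation along them); [icp_register()] refuses such geometry.
#' @export
linearized_point_to_plane_step <- function(p, q, n) {
  if (nrow(p) < 6) stop("need at least 6 correspondences")
  cxn <- cbind(p[, 2] * n[, 3] - p[, 3] * n[, 2],
               p[, 3] * n[, 1] - p[, 1] * n[, 3],
               p[, 1] * n[, 2] - p[, 2] * n[, 1])
  A <- cbind(cxn, n)
  b <- rowSums((q - p) * n)
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d > max(tol, 0)
  rank <- sum(keep)
  x <- if (rank == 0) numeric(6)
       else sv$v[, keep, drop = FALSE] %*%
            (crossprod(sv$u[, keep, drop = FALSE], b) / sv$d[keep])
  x <- as.numeric(x)
  structure(rigid_transform(axis_angle_rotation(x[1:3]), x[4:6]), rank = rank)
}

# exact rotation exponential of a rotation vector (Rodrigues)
axis_angle_rotation <- function(w) {
  theta <- sqrt(sum(w^2))
  if (theta < 1e-300) return(diag(3))
  k <- w / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rigid superimposition by point-to-plane ICP
#'
#' Iteratively registers `moving` onto `fixed`: each iteration matches the
#' (current) reference vertices of the moving mesh to their exact closest
#' points on the fixed surface, then minimizes the point-to-plane objective
#' `sum(((R p + t - q) . n_q)^2)` by a linearized update. The objective is
#' evaluated before each update, giving a monotone convergence trace on
#' well-posed problems. With `overlap < 1` the worst `(1 - overlap)` fraction
#' of correspondences by distance is discarded each iteration.
#'
#' @param moving,fixed [tri_mesh()] objects (moving = test/segmented model,
#'   fixed = reference model).
#' @param reference reference area driving the fit: `NULL` for the whole
#'   moving mesh, an integer vector of moving-mesh vertex indices, or a list
#'   of region patches (see [grow_patch()]) on the moving mesh.
#' @param settings an [icp_settings()].
#' @param init initialization: `"identity"` (the default; segmented and
#'   reference models share a frame in this workflow, either the volume
#'   frame or a prior coarse alignment) or `"centroid"` (translate the
#'   full-mesh centroids together first).
#' @return list with `transform` (the [rigid_transform()] mapping `moving`
#'   into `fixed`'s frame), `trace` (objective per iteration, RMS mm),
#'   `iterations` used, and `converged`.
#' @export
icp_register <- function(moving, fixed, reference = NULL,
                         settings = icp_settings(), init = c("identity", "centroid")) {
  init <- match.arg(init)
  if (nrow(moving$faces) == 0L || nrow(fixed$faces) == 0L) stop("empty mesh")
  idx <- reference_vertices(moving, reference)
  if (settings$sampling < 1) {
    n_keep <- max(6L, ceiling(settings$sampling * length(idx)))
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(settings$seed)
    idx <- sort(sample(idx, n_keep))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }
  if (length(idx) < 6) stop("reference area has fewer than 6 vertices")
  p0 <- moving$vertices[idx, , drop = FALSE]
  check_not_degenerate(p0)

  tree <- mesh_index(fixed)
  fn <- face_normals(fixed)

  transform <- rigid_transform()
  if (init == "centroid") {
    transform <- rigid_transform(diag(3),
                                 colMeans(fixed$vertices) - colMeans(moving$vertices))
  }
  trace <- numeric(0)
  prev_obj <- Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(settings$iterations)) {
    iters <- it
    p <- transform_points(p0, transform)
    hit <- closest_point(NULL, p, index = tree)
    keep <- seq_len(nrow(p))
    if (settings$overlap < 1) {
      n_keep <- max(6L, ceiling(settings$overlap * nrow(p)))
      keep <- order(hit$distance)[seq_len(n_keep)]
    }
    q <- hit$point[keep, , drop = FALSE]
    nq <- fn[hit$face[keep], , drop = FALSE]
    resid <- rowSums((p[keep, , drop = FALSE] - q) * nq)
    obj <- sqrt(mean(resid^2))
    if (!is.finite(obj)) stop("non-finite ICP objective")
    trace <- c(trace, obj)
    if (is.finite(prev_obj)) {
      denom <- max(prev_obj, .Machine$double.eps)
      if (abs(prev_obj - obj) / denom < settings$tolerance || obj == 0) {
        converged <- TRUE
        break
      }
    }
    prev_obj <- obj
    step <- linearized_point_to_plane_step(p[keep, , drop = FALSE], q, nq)
    if (it == 1L && attr(step, "rank") < 6)
      stop("degenerate reference area: rank-deficient normal span ",
           "(coplanar or otherwise under-constraining geometry)")
    transform <- compose_transform(step, transform)
  }
  list(transform = transform, trace = trace, iterations = iters,
       converged = converged)
}

reference_vertices <- function(mesh, reference) {
  if (is.null(reference)) return(seq_len(nrow(mesh$vertices)))
  if (is.numeric(reference)) return(as.integer(reference))
  if (inherits(reference, "region_patch")) reference <- list(reference)
  sort(unique(unlist(lapply(reference, function(p) p$vertices))))
}

check_not_degenerate <- function(p) {
  s <- svd(sweep(p, 2, colMeans(p)))$d
  if (s[2] < 1e-9 * max(s[1], 1))
    stop("degenerate reference area: points are collinear")
}
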