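# Fixture builders and independent geometric oracles, constructed in code.

# axis-aligned unit cube, consistently outward-oriented
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  colnames(v) <- NULL
  quads <- list(
    c(1, 2, 4, 3),  # z = 0, outward -z
    c(5, 7, 8, 6),  # z = 1, outward +z
    c(1, 5, 6, 2),  # y = 0
    c(3, 4, 8, 7),  # y = 1
    c(1, 3, 7, 5),  # x = 0
    c(2, 6, 8, 4))  # x = 1
  f <- do.call(rbind, lapply(quads, function(q)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  m <- tri_mesh(v, f)
  # orient outward (positive enclosed volume)
  if (surfaccuracy:::signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# flat triangulated grid in the z = 0 plane
plane_grid <- function(n = 10, spacing = 1, z = 0) {
  g <- expand.grid(x = 0:n, y = 0:n)
  v <- cbind(g$x * spacing, g$y * spacing, z)
  id <- function(i, j) i + 1 + (n + 1) * j
  f <- do.call(rbind, lapply(0:(n - 1), function(j) {
    do.call(rbind, lapply(0:(n - 1), function(i) {
      rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
            c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    }))
  }))
  tri_mesh(v, f)
}

# unit icosphere by subdivision; 20 * 4^level faces, vertices on the sphere
icosphere <- function(level = 2, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(level)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    f <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
      a <- f[i, 1]; b <- f[i, 2]; c2 <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c2); ca <- midpoint(c2, a)
      rbind(c(a, ab, ca), c(b, bc, ab), c(c2, ca, bc), c(ab, bc, ca))
    }))
  }
  m <- tri_mesh(v * radius, f)
  if (surfaccuracy:::signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# Independent closest-point oracle: per face, project onto the plane; if the
# barycentric coordinates are inside, take the projection, else the nearest
# point on the three edge segments. Deliberately a different formulation
# from the package's region-based kernel.
brute_closest <- function(mesh, q) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c2 <- v[f[, 3], , drop = FALSE]
  seg_closest <- function(p0, p1, q) {
    d <- p1 - p0
    tt <- rowSums(sweep(d, 2, q, `*`) - d * p0) / pmax(rowSums(d^2), 1e-300)
    tt <- pmin(pmax(tt, 0), 1)
    p0 + d * tt
  }
  e1 <- b - a
  e2 <- c2 - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  qa <- sweep(-a, 2, q, `+`)
  tproj <- rowSums(qa * nrm) / rowSums(nrm^2)
  proj <- sweep(nrm * -tproj, 2, q, `+`)
  # barycentric of the projection
  d00 <- rowSums(e1 * e1); d01 <- rowSums(e1 * e2); d11 <- rowSums(e2 * e2)
  pv <- proj - a
  d20 <- rowSums(pv * e1); d21 <- rowSums(pv * e2)
  den <- d00 * d11 - d01 * d01
  bv <- (d11 * d20 - d01 * d21) / den
  bw <- (d00 * d21 - d01 * d20) / den
  inside <- bv >= 0 & bw >= 0 & bv + bw <= 1
  cand <- proj
  if (any(!inside)) {
    i <- which(!inside)
    e_ab <- seg_closest(a[i, , drop = FALSE], b[i, , drop = FALSE], q)
    e_bc <- seg_closest(b[i, , drop = FALSE], c2[i, , drop = FALSE], q)
    e_ca <- seg_closest(c2[i, , drop = FALSE], a[i, , drop = FALSE], q)
    d_ab <- rowSums(sweep(e_ab, 2, q)^2)
    d_bc <- rowSums(sweep(e_bc, 2, q)^2)
    d_ca <- rowSums(sweep(e_ca, 2, q)^2)
    pick <- cbind(d_ab, d_bc, d_ca)
    best <- max.col(-pick, ties.method = "first")
    repl <- e_ab
    repl[best == 2, ] <- e_bc[best == 2, , drop = FALSE]
    repl[best == 3, ] <- e_ca[best == 3, , drop = FALSE]
    cand[i, ] <- repl
  }
  d2 <- rowSums(sweep(cand, 2, q)^2)
  k <- which.min(d2)
  list(distance = unname(sqrt(d2[k])), point = unname(cand[k, ]), face = k)
}

# number of crossings of segment p0 -> p1 with the mesh (Moller-Trumbore)
segment_crossings <- function(mesh, p0, p1) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  d <- p1 - p0
  cross_vec <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                    u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                    u[, 1] * w[, 2] - u[, 2] * w[, 1])
  dm <- matrix(d, nrow(a), 3, byrow = TRUE)
  pvec <- cross_vec(dm, e2)
  det <- rowSums(e1 * pvec)
  tvec <- sweep(-a, 2, p0, `+`)
  u <- rowSums(tvec * pvec) / det
  qvec <- cross_vec(tvec, e1)
  vv <- rowSums(sweep(qvec, 2, d, `*`)) / det
  tt <- rowSums(e2 * qvec) / det
  hit <- abs(det) > 1e-300 & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt >= 0 & tt <= 1
  sum(hit, na.rm = TRUE)
}

# spherical volume with the analytic signed field R - r
sphere_volume <- function(h, R = 10, pad = 2) {
  g <- seq(-(R + pad), R + pad, by = h)
  n <- length(g)
  r <- sqrt(outer(outer(g^2, g^2, `+`), g^2, `+`))
  scan_volume(R - r, rep(h, 3), origin = rep(-(R + pad), 3))
}

random_motion <- function(max_angle = 10, max_trans = 3) {
  list(rx = runif(1, -max_angle, max_angle),
       ry = runif(1, -max_angle, max_angle),
       rz = runif(1, -max_angle, max_angle),
       tx = runif(1, -max_trans, max_trans),
       ty = runif(1, -max_trans, max_trans),
       tz = runif(1, -max_trans, max_trans))
}

# coarse phantom shared across tests (built once per session)
.test_cache <- new.env()
test_phantom <- function() {
  if (is.null(.test_cache$phantom)) {
    .test_cache$phantom <- make_phantom(phantom_spec(seed = 11),
                                        n_rings = 26, n_around = 90,
                                        patch_size = 400)
  }
  .test_cache$phantom
}
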