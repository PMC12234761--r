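#' Triangle surface mesh
#'
#' The universal currency of the pipeline: an indexed triangle mesh with
#' vertex coordinates in millimetres. Faces are 1-based triples of vertex
#' indices. Optional unit vertex normals may be attached (and are computed
#' on demand by [vertex_normals()]).
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param faces integer matrix, m x 3, vertex indices (1-based).
#' @param normals optional numeric matrix, n x 3, unit vertex normals.
#' @param check validate invariants (index bounds, degenerate faces)?
#' @param area_epsilon faces with area below this (mm^2) count as degenerate.
#'
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL, check = TRUE,
                     area_epsilon = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
  mesh <- structure(list(vertices = vertices, faces = faces, normals = normals),
                    class = "tri_mesh")
  if (check) validate_mesh(mesh, area_epsilon = area_epsilon)
  mesh
}

#' Validate triangle-mesh invariants
#'
#' Checks that every face index addresses an existing vertex, that faces have
#' three distinct vertices, and that no face is degenerate (area below
#' `area_epsilon`).
#'
#' @inheritParams tri_mesh
#' @param mesh a [tri_mesh()].
#' @return `mesh`, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh, area_epsilon = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) == 0L || nrow(f) == 0L) stop("empty mesh: no vertices or faces")
  if (any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (any(f < 1L) || any(f > nrow(v))) stop("face index out of vertex range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate face: repeated vertex index")
  a <- face_areas(mesh)
  if (any(a <= area_epsilon))
    stop(sprintf("degenerate face: %d face(s) with area <= %g mm^2",
                 sum(a <= area_epsilon), area_epsilon))
  invisible(mesh)
}

#' @export
print.tri_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("tri_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox (mm): x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  cat(sprintf("  surface area: %.3f mm^2\n", sum(face_areas(x))))
  invisible(x)
}

#' Mesh summary statistics
#'
#' @param mesh a [tri_mesh()].
#' @return list with vertex/face counts, bounding box (mm) and total area (mm^2).
#' @export
mesh_summary <- function(mesh) {
  list(n_vertices = nrow(mesh$vertices),
       n_faces = nrow(mesh$faces),
       bbox = apply(mesh$vertices, 2, range),
       area = sum(face_areas(mesh)))
}

# cross products of the two edge vectors of every face (not normalized);
# norm/2 is the face area, direction the face normal
face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Face areas and unit face normals
#'
#' @param mesh a [tri_mesh()].
#' @return `face_areas`: numeric vector of areas (mm^2). `face_normals`:
#'   m x 3 matrix of unit normals (right-hand rule over the vertex order).
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  sqrt(rowSums(cr^2)) / 2
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  n <- sqrt(rowSums(cr^2))
  n[n == 0] <- 1
  cr / n
}

#' Per-vertex unit normals
#'
#' Area-weighted average of the incident face normals, normalized to unit
#' length. Isolated vertices (no incident face with nonzero area) get a zero
#' normal and trigger a warning.
#'
#' @param mesh a [tri_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh)  # area-weighted face normal = cross / 2
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (col in 1:3) {
    idx <- mesh$faces[, col]
    for (d in 1:3) {
      acc <- rowsum(cr[, d], idx)
      rows <- as.integer(rownames(acc))
      n[rows, d] <- n[rows, d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  zero <- len < 1e-300
  if (any(zero))
    warning(sprintf("%d isolated or flat vertex normals set to zero", sum(zero)))
  len[zero] <- 1
  n / len
}

#' Closest point on a mesh surface
#'
#' Finds, for each query point, the exact closest point on the mesh surface
#' (triangle interiors, edges and vertices all considered), via an
#' axis-aligned bounding-box tree over the faces. The tree prunes but never
#' approximates: the reported distance is the global minimum over all
#' triangles.
#'
#' @param mesh a [tri_mesh()].
#' @param query numeric vector of length 3, or k x 3 matrix of query points (mm).
#' @param index optional prebuilt index from [mesh_index()] (for repeated
#'   queries against the same mesh, e.g. inside ICP).
#' @return list with components `distance` (k), `point` (k x 3 closest
#'   surface positions), `face` (k, 1-based face index), `bary` (k x 3
#'   barycentric coordinates within that face).
#' @export
closest_point <- function(mesh, query, index = NULL) {
  if (is.null(dim(query))) query <- matrix(query, ncol = 3)
  query <- as.matrix(query)
  storage.mode(query) <- "double"
  if (is.null(index)) {
    if (nrow(mesh$faces) == 0L) stop("empty mesh")
    cpp_closest_points(mesh$vertices, mesh$faces, query)
  } else {
    cpp_aabb_query(index, query)
  }
}

#' Build a reusable spatial index for closest-point queries
#'
#' @param mesh a [tri_mesh()].
#' @return an opaque index handle accepted by [closest_point()].
#' @export
mesh_index <- function(mesh) {
  if (nrow(mesh$faces) == 0L) stop("empty mesh")
  cpp_aabb_build(mesh$vertices, mesh$faces)
}

#' Merge duplicate vertices within a tolerance
#'
#' STL stores each facet's corners independently; welding restores shared
#' vertices. Vertices are snapped to a grid of cell size `tol` and merged per
#' cell; faces that collapse to fewer than three distinct vertices are dropped.
#'
#' @param mesh a [tri_mesh()].
#' @param tol weld tolerance in mm.
#' @return a welded [tri_mesh()].
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  newv <- v[first, , drop = FALSE]
  newf <- matrix(map[mesh$faces], ncol = 3)
  ok <- newf[, 1] != newf[, 2] & newf[, 2] != newf[, 3] & newf[, 1] != newf[, 3]
  tri_mesh(newv, newf[ok, , drop = FALSE], check = FALSE)
}

#' Apply a rigid transform to a mesh or point set
#'
#' @param x a [tri_mesh()] or an n x 3 point matrix.
#' @param transform a [rigid_transform()].
#' @return the transformed object, same type as `x`.
#' @export
transform_mesh <- function(x, transform) {
  if (inherits(x, "tri_mesh")) {
    out <- x
    out$vertices <- transform_points(x$vertices, transform)
    if (!is.null(out$normals))
      out$normals <- out$normals %*% t(transform$rotation)
    out
  } else {
    transform_points(x, transform)
  }
}

transform_points <- function(p, transform) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  sweep(p %*% t(transform$rotation), 2, transform$translation, `+`)
}
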