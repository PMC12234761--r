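#' Region specification: a seed-defined circular surface patch
#'
#' Measurement and superimposition areas are circular patches of a fixed
#' triangle count (1000 by default) grown around a seed on the surface.
#'
#' @param seed length-3 seed point (mm), or a single vertex index when
#'   `seed_is_vertex = TRUE`.
#' @param size patch size in triangles (>= 1).
#' @param label optional label, e.g. `"ACB-left-1"`.
#' @param seed_is_vertex interpret `seed` as a vertex id of the target mesh?
#' @return object of class `region_spec`.
#' @export
region_spec <- function(seed, size = 1000, label = NULL, seed_is_vertex = FALSE) {
  stopifnot(size >= 1)
  if (!seed_is_vertex && length(seed) != 3)
    stop("`seed` must be a 3D point (or a vertex id with seed_is_vertex = TRUE)")
  structure(list(seed = seed, size = as.integer(size), label = label,
                 seed_is_vertex = seed_is_vertex),
            class = "region_spec")
}

# face adjacency over shared edges, as a list face -> neighbouring faces
face_adjacency <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  fid <- rep(seq_len(m), 3)
  o <- order(a, b)
  a <- a[o]; b <- b[o]; fo <- fid[o]
  n <- length(a)
  same <- a[-1] == a[-n] & b[-1] == b[-n]
  pairs <- cbind(fo[-n][same], fo[-1][same])
  adj <- vector("list", m)
  sp <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
  adj[as.integer(names(sp))] <- sp
  adj
}

#' Grow a circular measurement patch around a seed
#'
#' Starting from the face nearest to the seed, faces are added one at a time
#' over the face-adjacency graph, always taking the frontier face whose
#' centroid is nearest the seed (a geodesic-approximating order), until the
#' patch holds exactly `spec$size` faces. Ties break on the lower face index,
#' so the result is deterministic.
#'
#' @param mesh a [tri_mesh()].
#' @param spec a [region_spec()].
#' @param index,adjacency optional precomputed [mesh_index()] and internal
#'   face adjacency, reused by [grow_patches()] across seeds.
#' @return object of class `region_patch`: list with `faces` (face indices),
#'   `vertices` (member vertex ids), `label`, and `truncated` (TRUE when the
#'   mesh has fewer faces than requested).
#' @export
grow_patch <- function(mesh, spec, index = NULL, adjacency = NULL) {
  m <- nrow(mesh$faces)
  if (spec$seed_is_vertex) {
    seed_pt <- mesh$vertices[spec$seed, ]
  } else {
    seed_pt <- as.numeric(spec$seed)
  }
  hit <- closest_point(mesh, seed_pt, index = index)
  seed_face <- hit$face[1]

  size <- spec$size
  truncated <- FALSE
  if (size > m) {
    warning(sprintf("patch size %d exceeds mesh size %d: truncating", size, m))
    size <- m
    truncated <- TRUE
  }

  cent <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
           mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
           mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  d2 <- (cent[, 1] - seed_pt[1])^2 + (cent[, 2] - seed_pt[2])^2 +
        (cent[, 3] - seed_pt[3])^2

  nbr <- if (is.null(adjacency)) face_adjacency(mesh) else adjacency

  in_patch <- logical(m)
  in_front <- logical(m)
  in_patch[seed_face] <- TRUE
  frontier <- unique(nbr[[seed_face]])
  in_front[frontier] <- TRUE
  taken <- seed_face
  while (length(taken) < size) {
    if (length(frontier) == 0) {
      warning("patch growth exhausted a connected component before reaching the requested size")
      truncated <- TRUE
      break
    }
    best <- frontier[order(d2[frontier], frontier)[1]]
    in_patch[best] <- TRUE
    in_front[best] <- FALSE
    taken <- c(taken, best)
    new_n <- nbr[[best]]
    new_n <- new_n[!in_patch[new_n] & !in_front[new_n]]
    frontier <- c(frontier[frontier != best], unique(new_n))
    in_front[new_n] <- TRUE
  }
  faces <- sort(taken)
  structure(list(faces = faces,
                 vertices = sort(unique(as.vector(mesh$faces[faces, ]))),
                 label = spec$label, truncated = truncated),
            class = "region_patch")
}

#' Grow several patches on the same mesh
#'
#' Computes the spatial index and face adjacency once and grows one patch
#' per spec.
#'
#' @param mesh a [tri_mesh()].
#' @param specs list of [region_spec()] objects.
#' @return list of `region_patch` objects.
#' @export
grow_patches <- function(mesh, specs) {
  idx <- mesh_index(mesh)
  adj <- face_adjacency(mesh)
  lapply(specs, function(s) grow_patch(mesh, s, index = idx, adjacency = adj))
}

#' Per-vertex distances from one mesh to another
#'
#' For every source-mesh vertex in the region set, the unsigned distance to
#' the exact closest point on the target surface, plus a signed variant
#' (positive outside the target surface, by the target's face normal at the
#' closest point). Meshes must already be in the same frame: either their
#' original volume positions (pre-superimposition assessment) or after
#' registration.
#'
#' @param source,target [tri_mesh()] objects; distances run from `source`
#'   vertices to the `target` surface.
#' @param regions `NULL` for all source vertices, or a list of
#'   [grow_patch()] patches on `source`.
#' @return data.frame of class `distance_field` with columns `vertex`,
#'   `distance` (unsigned, mm), `signed` (mm), `region`.
#' @export
distance_field <- function(source, target, regions = NULL) {
  if (!is.null(regions)) {
    if (inherits(regions, "region_patch")) regions <- list(regions)
    if (length(regions) == 0) stop("empty region set")
    vid <- unlist(lapply(regions, function(p) p$vertices))
    lab <- rep(vapply(seq_along(regions), function(i) {
      if (is.null(regions[[i]]$label)) paste0("region", i) else regions[[i]]$label
    }, character(1)), vapply(regions, function(p) length(p$vertices), integer(1)))
    dup <- duplicated(vid)  # a vertex on a patch border belongs to its first patch
    vid <- vid[!dup]
    lab <- lab[!dup]
  } else {
    vid <- seq_len(nrow(source$vertices))
    lab <- rep("all", length(vid))
  }
  hit <- closest_point(target, source$vertices[vid, , drop = FALSE])
  fn <- face_normals(target)[hit$face, , drop = FALSE]
  sgn <- sign(rowSums((source$vertices[vid, , drop = FALSE] - hit$point) * fn))
  out <- data.frame(vertex = vid, distance = hit$distance,
                    signed = sgn * hit$distance, region = lab)
  class(out) <- c("distance_field", "data.frame")
  out
}

#' MAD and SDAD of a distance field
#'
#' The mean absolute distance (MAD) is the mean of the unsigned vertex
#' distances pooled over all regions; the SDAD is the standard deviation of
#' those absolute distances (population denominator `n`; immaterial at
#' thousands of vertices and documented here for exactness). Per-region
#' values are returned alongside for diagnostics.
#'
#' @param field a [distance_field()].
#' @return object of class `accuracy_result`: list with `mad`, `sdad`,
#'   `n_vertices`, and `per_region` (data.frame with region, mad, sdad, n).
#' @export
mad_sdad <- function(field) {
  if (nrow(field) == 0) stop("empty distance field")
  d <- abs(field$distance)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  per <- do.call(rbind, lapply(split(d, field$region), function(x)
    data.frame(mad = mean(x), sdad = pop_sd(x), n = length(x))))
  per <- data.frame(region = rownames(per), per, row.names = NULL)
  structure(list(mad = mean(d), sdad = pop_sd(d), n_vertices = length(d),
                 per_region = per),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("MAD %.6f mm, SDAD %.6f mm over %d vertices in %d region(s)\n",
              x$mad, x$sdad, x$n_vertices, nrow(x$per_region)))
  invisible(x)
}

#' Export a per-vertex distance map
#'
#' Writes the mesh with its per-vertex scalar distances as an ASCII PLY
#' (property `quality`; vertices outside the field carry NA encoded as the
#' value `na_value`) plus a CSV of vertex id, unsigned and signed distance.
#' The colour windows used for map display (for example 0.1, 0.04 or 0.2 mm)
#' are recorded in the CSV header comment via `scale_limit`.
#'
#' @param field a [distance_field()] computed from `mesh`'s vertices.
#' @param mesh the source [tri_mesh()].
#' @param path output path; `.ply` is written there, and a sibling `.csv`
#'   next to it.
#' @param scale_limit display window (mm) recorded with the map.
#' @param signed write signed distances instead of unsigned?
#' @param na_value scalar stored for vertices not in the field.
#' @return invisible list with the two paths written.
#' @export
export_distance_map <- function(field, mesh, path, scale_limit = 0.1,
                                signed = FALSE, na_value = 0) {
  scalar <- rep(na_value, nrow(mesh$vertices))
  scalar[field$vertex] <- if (signed) field$signed else field$distance
  write_ply(mesh, path, scalar = scalar, scalar_name = "quality")
  csv_path <- paste0(tools::file_path_sans_ext(path), ".csv")
  con <- file(csv_path, "w")
  writeLines(sprintf("# distance map, scale_limit_mm=%g", scale_limit), con)
  utils::write.csv(field, con, row.names = FALSE)
  close(con)
  invisible(list(ply = path, csv = csv_path))
}

#' Read back an exported distance map
#'
#' @param path the `.ply` written by [export_distance_map()].
#' @return list with `mesh` and `scalar` (per-vertex distances).
#' @export
read_distance_map <- function(path) {
  read_ply(path)
}
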