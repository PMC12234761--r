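#' Extract a bone surface at a single grey-value threshold
#'
#' Triangulates the level set `{value = t}` of a volume with a marching-cubes
#' variant: each voxel cell is decomposed into six tetrahedra and the surface
#' is linearly interpolated along tetrahedron edges, which resolves the
#' classic cube ambiguities by construction and yields a watertight mesh away
#' from the volume boundary. The mesh bounds the region with `value >= t`
#' (its "outer skeletal surface"), with normals pointing out of that region.
#' Vertex coordinates are physical millimetres (spacing and origin applied).
#' No smoothing or decimation is applied.
#'
#' @param vol a [scan_volume()].
#' @param threshold iso level, strictly inside the volume's grey range and
#'   crossed by the data.
#' @param largest_component keep only the largest connected surface
#'   component (off by default; requires the igraph package).
#' @return a [tri_mesh()].
#' @export
extract_isosurface <- function(vol, threshold, largest_component = FALSE) {
  rng <- range(vol$values)
  if (threshold <= rng[1] || threshold >= rng[2])
    stop(sprintf("threshold %g produces no surface: data range is [%g, %g]",
                 threshold, rng[1], rng[2]))
  d <- dim(vol$values)
  res <- cpp_marching_tets(as.numeric(vol$values), d[1], d[2], d[3], threshold)
  if (nrow(res$faces) == 0L)
    stop(sprintf("threshold %g produces no surface crossings", threshold))
  verts <- sweep(sweep(res$vertices, 2, vol$spacing, `*`), 2, vol$origin, `+`)
  mesh <- tri_mesh(verts, res$faces, check = FALSE)
  if (largest_component) mesh <- keep_largest_component(mesh)
  mesh
}

keep_largest_component <- function(mesh) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("largest-component filtering requires the igraph package")
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)$membership
  keep_comp <- which.max(tabulate(comp[f[, 1]]))
  keep_faces <- comp[f[, 1]] == keep_comp
  f2 <- f[keep_faces, , drop = FALSE]
  used <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tri_mesh(mesh$vertices[used, , drop = FALSE],
           matrix(remap[f2], ncol = 3), check = FALSE)
}

#' Suggest a segmentation threshold between bone and background
#'
#' A deterministic stand-in for the visual threshold choice: maximises the
#' between-class variance (Otsu's criterion) of the grey-value histogram over
#' the probe slices, returning a grey value between the background/water and
#' bone modes. If the histogram is effectively unimodal the midpoint of the
#' data range is returned with a warning.
#'
#' @param vol a [scan_volume()].
#' @param probe_slices indices of z-slices to histogram (default: all).
#' @param n_bins histogram resolution.
#' @return a single grey value.
#' @export
suggest_threshold <- function(vol, probe_slices = NULL, n_bins = 256) {
  vals <- if (is.null(probe_slices)) as.numeric(vol$values)
          else as.numeric(vol$values[, , probe_slices])
  rng <- range(vals)
  if (diff(rng) == 0) {
    warning("constant volume: returning midpoint of the grey range")
    return(mean(vol$value_range))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(vals, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)                 # class probability below cut
  cm <- cumsum(w * mids)          # class mean mass below cut
  mu <- cm[n_bins]
  valid <- cw > 0 & cw < 1
  bcv <- (mu * cw - cm)^2 / (cw * (1 - cw))
  bcv[!valid] <- -Inf
  # the criterion is flat across an empty valley between two sharp modes:
  # take the centre of the maximal plateau (deterministic)
  ks <- which(bcv >= max(bcv) - 1e-12 * abs(max(bcv)))
  k <- ks[ceiling(length(ks) / 2)]
  thr <- breaks[k + 1]
  # unimodality guard: Otsu on a unimodal histogram splits the single mode;
  # flag when the two classes are not separated by a clear valley
  lo <- counts[seq_len(k)]
  hi <- counts[(k + 1):n_bins]
  valley <- min(counts[max(1, k - 2):min(n_bins, k + 2)])
  if (valley > 0.5 * min(max(lo), max(hi))) {
    warning("histogram looks unimodal: returning midpoint of the grey range")
    return(mean(rng))
  }
  thr
}
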