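#' Read a triangle mesh from STL or OBJ
#'
#' STL may be binary or ASCII (auto-detected: a file is binary when its size
#' matches the 84 + 50 * n_facets layout). OBJ support covers vertices and
#' triangular faces only (`v` / `f` records; `f` entries of the form
#' `i`, `i/t` or `i/t/n` use the vertex index). STL facets do not share
#' vertices; pass `weld = TRUE` to merge duplicates within `weld_tol`.
#'
#' @param path file path.
#' @param format `"stl"`, `"obj"`, or `NULL` to infer from the extension.
#' @param weld merge duplicate vertices after reading? Off by default: the
#'   distance metrics are defined per stored vertex.
#' @param weld_tol weld tolerance in mm.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path, format = NULL, weld = FALSE, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  mesh <- switch(format,
    stl = read_stl(path),
    obj = read_obj(path),
    ply = read_ply(path)$mesh,
    stop("unsupported mesh format: ", format))
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("empty mesh in ", path)
  if (weld) mesh <- weld_vertices(mesh, tol = weld_tol)
  validate_mesh(mesh)
  mesh
}

#' Write a triangle mesh to STL or OBJ
#'
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param format `"stl"` (binary by default), `"stl_ascii"`, or `"obj"`;
#'   `NULL` infers binary STL / OBJ from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L)
    stop("refusing to write an empty mesh")
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)), obj = "obj", "stl")
  switch(format,
    stl = write_stl_binary(mesh, path),
    stl_ascii = write_stl_ascii(mesh, path),
    obj = write_obj(mesh, path),
    stop("unsupported mesh format: ", format))
  invisible(path)
}

is_binary_stl <- function(path) {
  size <- file.info(path)$size
  if (size < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  !is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri)
}

read_stl <- function(path) {
  if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  raw_body <- readBin(con, "raw", 50 * ntri)
  if (length(raw_body) != 50 * ntri)
    stop(sprintf("malformed binary STL %s: body truncated at byte %d (expected %d facets)",
                 path, 84 + length(raw_body), ntri))
  # each facet: 12 floats (normal + 3 vertices) + uint16 attribute
  m <- matrix(raw_body, nrow = 50)
  floats <- readBin(as.vector(m[1:48, ]), "numeric", n = 12 * ntri, size = 4,
                    endian = "little")
  fm <- matrix(floats, nrow = 12)  # rows 4..12 are the three vertices
  verts <- matrix(as.vector(fm[4:12, ]), ncol = 3, byrow = TRUE)
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces, check = FALSE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop(sprintf("malformed ASCII STL %s: %d vertex lines (first offender near line %d)",
                 path, length(vl), if (length(vl)) vl[1] else 1))
  toks <- strsplit(trimws(lines[vl]), "\\s+")
  verts <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (any(!is.finite(verts)))
    stop(sprintf("malformed ASCII STL %s: non-numeric vertex near line %d",
                 path, vl[which(!is.finite(rowSums(verts)))[1]]))
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  tri_mesh(verts, faces, check = FALSE)
}

write_stl_binary <- function(mesh, path) {
  con <- tryCatch(file(path, "wb"), error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "binary STL"))[1:80]
  writeBin(header, con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  fn <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  # 12 floats per facet: normal, v1, v2, v3
  block <- rbind(t(fn), t(v[f[, 1], , drop = FALSE]), t(v[f[, 2], , drop = FALSE]),
                 t(v[f[, 3], , drop = FALSE]))
  raw_f <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
  attr_r <- writeBin(integer(nf), raw(), size = 2, endian = "little")
  fm <- matrix(raw(50 * nf), nrow = 50)
  fm[1:48, ] <- matrix(raw_f, nrow = 48)
  fm[49:50, ] <- matrix(attr_r, nrow = 2)
  writeBin(as.vector(fm), con)
  invisible(path)
}

write_stl_ascii <- function(mesh, path) {
  fn <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]), con)
    writeLines("    outer loop", con)
    for (j in 1:3) {
      p <- v[f[i, j], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
    }
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines)
  fl <- grep("^f\\s", lines)
  if (length(vl) == 0 || length(fl) == 0)
    stop("malformed OBJ ", path, ": no vertices or faces")
  vt <- strsplit(trimws(lines[vl]), "\\s+")
  verts <- t(vapply(vt, function(tk) as.numeric(tk[2:4]), numeric(3)))
  ft <- strsplit(trimws(lines[fl]), "\\s+")
  faces <- t(vapply(seq_along(ft), function(i) {
    tk <- ft[[i]][-1]
    if (length(tk) != 3)
      stop(sprintf("malformed OBJ %s: non-triangular face at line %d", path, fl[i]))
    idx <- as.integer(vapply(strsplit(tk, "/"), `[`, character(1), 1))
    if (any(is.na(idx)))
      stop(sprintf("malformed OBJ %s: bad face index at line %d", path, fl[i]))
    idx
  }, integer(3)))
  neg <- faces < 0L
  faces[neg] <- nrow(verts) + 1L + faces[neg]  # OBJ relative indexing
  tri_mesh(verts, faces, check = FALSE)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

# ASCII PLY with an optional per-vertex scalar property ("quality"); used for
# distance maps and their round-trip tests.
write_ply <- function(mesh, path, scalar = NULL, scalar_name = "quality") {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z"), con)
  if (!is.null(scalar)) {
    stopifnot(length(scalar) == nrow(v))
    writeLines(sprintf("property double %s", scalar_name), con)
  }
  writeLines(c(sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (is.null(scalar)) {
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  } else {
    writeLines(sprintf("%.17g %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3], scalar), con)
  }
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop("malformed PLY ", path, ": no end_header")
  hdr <- lines[seq_len(end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  vprops <- sub("^property \\S+ ", "", grep("^property (double|float)", hdr, value = TRUE))
  vlines <- lines[end + seq_len(nv)]
  vals <- matrix(as.numeric(unlist(strsplit(trimws(vlines), "\\s+"))),
                 ncol = length(vprops), byrow = TRUE)
  colnames(vals) <- vprops
  flines <- lines[end + nv + seq_len(nf)]
  ftok <- matrix(as.integer(unlist(strsplit(trimws(flines), "\\s+"))),
                 ncol = 4, byrow = TRUE)
  mesh <- tri_mesh(vals[, c("x", "y", "z"), drop = FALSE],
                   ftok[, 2:4, drop = FALSE] + 1L, check = FALSE)
  scalars <- setdiff(vprops, c("x", "y", "z"))
  list(mesh = mesh,
       scalar = if (length(scalars)) vals[, scalars[1]] else NULL)
}
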