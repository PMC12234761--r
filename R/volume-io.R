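#' Volumetric scan with physical spacing
#'
#' A 3D scalar grid of grey values with anisotropic voxel spacing (mm), a
#' physical origin (position of voxel `[1, 1, 1]`, mm) and the representable
#' grey-value range. The array is laid out `[x, y, z]`; the physical
#' coordinate of voxel `(i, j, k)` (1-based) is
#' `origin + ((i, j, k) - 1) * spacing`.
#'
#' @param values 3D numeric array of grey values, `[x, y, z]` order.
#' @param spacing numeric length-3, voxel spacing in mm; all components > 0.
#'   Anisotropic spacing is permitted (CT slices are commonly thicker than
#'   the in-plane sampling).
#' @param origin numeric length-3, physical position of the first voxel (mm).
#' @param value_range length-2 representable grey-value range; defaults to
#'   the data range. Must span all stored values.
#' @return An object of class `scan_volume`.
#' @export
scan_volume <- function(values, spacing, origin = c(0, 0, 0),
                        value_range = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes (mm)")
  if (is.null(value_range)) value_range <- range(values)
  value_range <- as.numeric(value_range)
  if (value_range[1] > min(values) || value_range[2] < max(values))
    stop("`value_range` does not span the stored grey values")
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin), value_range = value_range),
            class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("scan_volume: %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm): (%.4g, %.4g, %.4g); grey range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$value_range[1], x$value_range[2]))
  invisible(x)
}

#' Physical coordinates of voxel centres
#'
#' @param vol a [scan_volume()].
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of physical positions (mm).
#' @export
voxel_position <- function(vol, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Read a volumetric scan
#'
#' Supported containers: NRRD (raw little-endian or ascii encodings, the
#' subset this package writes) and NIfTI-1 (via RNifti). Spacing must be
#' present in the file metadata; there is no silent default.
#'
#' @param path file path.
#' @param format `"nrrd"`, `"nifti"`, or `NULL` to infer from the extension.
#' @return a [scan_volume()].
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, nrrd = "nrrd", nii = "nifti", gz = "nifti",
                     stop("cannot infer volume format from extension: ", ext))
  }
  switch(format,
    nrrd = read_nrrd(path),
    nifti = read_nifti_volume(path),
    stop("unsupported volume format: ", format))
}

#' Write a volumetric scan
#'
#' @param vol a [scan_volume()].
#' @param path output path.
#' @param format `"nrrd"` (raw little-endian doubles) or `"nifti"`; `NULL`
#'   infers from the extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, nrrd = "nrrd", nii = "nifti", gz = "nifti",
                     stop("cannot infer volume format from extension: ", ext))
  }
  switch(format,
    nrrd = write_nrrd(vol, path),
    nifti = write_nifti_volume(vol, path),
    stop("unsupported volume format: ", format))
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  keys <- list()
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0) stop("malformed NRRD ", path, ": header not terminated")
    if (line == "") break
    if (grepl("^#", line)) next
    if (grepl(":=", line)) {
      kv <- strsplit(line, ":=", fixed = TRUE)[[1]]
      keys[[trimws(kv[1])]] <- trimws(kv[2])
    } else {
      kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
    }
  }
  dims <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D NRRD volumes are supported")
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields$`space directions`)) {
    vecs <- regmatches(fields$`space directions`,
                       gregexpr("\\(([^)]*)\\)", fields$`space directions`))[[1]]
    mat <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    spacing <- sqrt(colSums(mat^2))
  }
  if (is.null(spacing) || any(!is.finite(spacing)))
    stop("NRRD ", path, " has no voxel spacing; refusing to assume one")
  origin <- c(0, 0, 0)
  if (!is.null(fields$`space origin`))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields$`space origin`), ",")[[1]])
  n <- prod(dims)
  type <- fields$type
  enc <- tolower(fields$encoding)
  if (enc == "raw") {
    vals <- switch(type,
      double = readBin(con, "numeric", n, size = 8, endian = "little"),
      float = readBin(con, "numeric", n, size = 4, endian = "little"),
      short = readBin(con, "integer", n, size = 2, endian = "little"),
      int = readBin(con, "integer", n, size = 4, endian = "little"),
      stop("unsupported NRRD type: ", type))
    if (length(vals) != n) stop("malformed NRRD ", path, ": truncated data")
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
    if (length(vals) != n) stop("malformed NRRD ", path, ": truncated data")
  } else stop("unsupported NRRD encoding: ", enc)
  vr <- NULL
  if (!is.null(keys[["value_range"]]))
    vr <- as.numeric(strsplit(keys[["value_range"]], "\\s+")[[1]])
  scan_volume(array(vals, dims), spacing, origin, value_range = vr)
}

write_nrrd <- function(vol, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  con <- tryCatch(file(path, "wb"), error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  d <- dim(vol$values)
  hdr <- c("NRRD0004",
           "# generated by surfaccuracy",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("spacings: %.17g %.17g %.17g",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3]),
           sprintf("space origin: (%.17g,%.17g,%.17g)",
                   vol$origin[1], vol$origin[2], vol$origin[3]),
           sprintf("encoding: %s", encoding),
           "endian: little",
           sprintf("value_range:= %.17g %.17g",
                   vol$value_range[1], vol$value_range[2]),
           "")
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.numeric(vol$values), con, size = 8, endian = "little")
  } else {
    writeLines(sprintf("%.17g", as.numeric(vol$values)), con, sep = "\n")
  }
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("only 3D NIfTI volumes are supported")
  arr <- array(as.numeric(arr), dim(arr))  # drop RNifti attributes
  spacing <- attr(img, "pixdim")[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI ", path, " has no positive voxel spacing; refusing to assume one")
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  # we write identity-orientation images; undo the RAS sign convention on read
  flip <- diag(xf[1:3, 1:3]) < 0
  d <- dim(arr)
  for (ax in which(flip)) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[ax]] <- rev(idx[[ax]])
    arr <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    origin[ax] <- origin[ax] - (d[ax] - 1) * spacing[ax]
  }
  scan_volume(arr, spacing, origin)
}

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Express a grey-value difference as a fraction of the representable range
#'
#' Segmentation thresholds live in scanner-specific grey-value units; to
#' compare threshold variability across devices, a difference is reported as
#' a fraction of the full representable range (so a difference of 10 on a
#' 4000-wide CT range is 0.25%).
#'
#' @param vol a [scan_volume()].
#' @param delta grey-value difference.
#' @return `delta / diff(value_range)` (a proportion; multiply by 100 for %).
#' @export
threshold_fraction <- function(vol, delta) {
  width <- diff(vol$value_range)
  if (width <= 0) stop("degenerate grey-value range: width is zero")
  delta / width
}
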