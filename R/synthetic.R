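# Synthetic stand-ins for the study materials: a thin curved bone-like shell
# with bilateral landmark seeds (the ground-truth "optical" surface), and a
# CT/CBCT acquisition simulator (voxelization, partial-volume blur,
# dose-dependent noise, operator threshold jitter).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else rm(".Random.seed", envir = .GlobalEnv)
  })
  force(expr)
}

#' Phantom specification: a thin curved bone-like shell
#'
#' The phantom emulates the anterior-cranial-base geometry at desk scale: a
#' thin (1.5 mm default) curved shell over an elliptical footprint, shaped as
#' a paraboloid bowl with sinusoidal ridge perturbations, with bilaterally
#' mirrored landmark seeds for the measurement and superimposition areas.
#' Axes follow the craniofacial convention: X lateral, Y vertical, Z
#' anteroposterior.
#'
#' @param thickness shell thickness in mm (thin, matching the thin skeletal
#'   structures the pipeline targets).
#' @param half_width,half_depth lateral (x) and anteroposterior (z)
#'   semi-axes of the elliptical footprint, mm.
#' @param bowl_depth height rise of the paraboloid from centre to rim, mm.
#' @param ridge_amplitude amplitude of the sinusoidal ridges, mm.
#' @param ridge_waves number of ridge periods across each semi-axis.
#' @param seed integer seed; randomizes the ridge phases only, so geometry
#'   is deterministic given the seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(thickness = 1.5, half_width = 16, half_depth = 12,
                         bowl_depth = 6, ridge_amplitude = 0.8,
                         ridge_waves = c(1.5, 1.0), seed = 1L) {
  stopifnot(thickness > 0, half_width > 0, half_depth > 0)
  structure(list(thickness = thickness, half_width = half_width,
                 half_depth = half_depth, bowl_depth = bowl_depth,
                 ridge_amplitude = ridge_amplitude, ridge_waves = ridge_waves,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# mid-surface height y = g(x, z) of the shell; even in x so the phantom is
# bilaterally symmetric like the anatomy it stands in for (the random phase
# varies the ridges anteroposteriorly only)
phantom_height <- function(spec, x, z, phases) {
  r2 <- (x / spec$half_width)^2 + (z / spec$half_depth)^2
  spec$bowl_depth * r2 +
    spec$ridge_amplitude *
      cos(pi * spec$ridge_waves[1] * x / spec$half_width) *
      sin(pi * spec$ridge_waves[2] * z / spec$half_depth + phases[2])
}

#' Generate the ground-truth phantom surface and its region seeds
#'
#' Builds a closed, consistently oriented triangle mesh of the shell (top
#' sheet, bottom sheet and rim wall over a polar parameter grid) together
#' with eight bilaterally mirrored measurement seeds and ten superimposition
#' seeds on the top surface. Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @param n_rings,n_around polar sampling of each sheet (controls truth-mesh
#'   resolution; defaults give roughly 0.3 mm edges).
#' @param patch_size triangle count for the generated region specs.
#' @return list with `mesh` (a [tri_mesh()]), `measurement` (8
#'   [region_spec()]s), `superimposition` (10 [region_spec()]s), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec(), n_rings = 44, n_around = 150,
                         patch_size = 1000) {
  phases <- with_seed(spec$seed, runif(2, 0, 2 * pi))
  h2 <- spec$thickness / 2

  nt <- n_around
  nr <- n_rings
  # one sheet: centre vertex + nr rings of nt vertices
  ring_r <- seq_len(nr) / nr
  theta <- 2 * pi * (seq_len(nt) - 1) / nt
  xs <- c(0, spec$half_width * rep(ring_r, each = nt) * cos(theta))
  zs <- c(0, spec$half_depth * rep(ring_r, each = nt) * sin(theta))
  g <- phantom_height(spec, xs, zs, phases)

  n_sheet <- 1L + nr * nt
  vid <- function(i, j) {  # ring i (0 = centre), slot j (wraps)
    if (i == 0L) rep(1L, length(j)) else 1L + (i - 1L) * nt + (j %% nt) + 1L
  }
  j <- 0:(nt - 1)
  fan <- cbind(vid(0L, 0L), vid(1L, j), vid(1L, j + 1))
  strips <- do.call(rbind, lapply(seq_len(nr - 1), function(i) {
    a <- vid(i, j); b <- vid(i, j + 1); c2 <- vid(i + 1L, j + 1); d <- vid(i + 1L, j)
    rbind(cbind(a, d, c2), cbind(a, c2, b))
  }))
  sheet_faces <- rbind(fan, strips)

  top_v <- cbind(xs, g + h2, zs)
  bot_v <- cbind(xs, g - h2, zs)
  top_f <- sheet_faces[, c(1, 3, 2)]       # normal towards +y
  bot_f <- sheet_faces + n_sheet           # normal towards -y
  # rim quads (t_j, t_{j+1}, b_{j+1}, b_j) -> two triangles
  tj <- vid(nr, j); tj1 <- vid(nr, j + 1)
  bj <- tj + n_sheet; bj1 <- tj1 + n_sheet
  rim_f <- rbind(cbind(tj, tj1, bj1), cbind(tj, bj1, bj))

  verts <- rbind(top_v, bot_v)
  faces <- rbind(top_f, bot_f, rim_f)
  mesh <- tri_mesh(verts, faces, check = FALSE)
  if (signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  validate_mesh(mesh)

  meas_frac <- rbind(c(0.45, -0.40), c(0.55, 0.10), c(0.25, 0.35), c(0.50, 0.45))
  meas <- list()
  for (i in seq_len(nrow(meas_frac))) {
    for (s in c(1, -1)) {
      x <- s * meas_frac[i, 1] * spec$half_width
      z <- meas_frac[i, 2] * spec$half_depth
      y <- phantom_height(spec, x, z, phases) + h2
      meas[[length(meas) + 1]] <- region_spec(
        c(x, y, z), size = patch_size,
        label = sprintf("ACB-%s-%d", if (s > 0) "right" else "left", i))
    }
  }
  sup_frac <- rbind(c(0.15, -0.15), c(0.35, -0.55), c(0.65, -0.10),
                    c(0.40, 0.25), c(0.15, 0.55))
  sup <- list()
  for (i in seq_len(nrow(sup_frac))) {
    for (s in c(1, -1)) {
      x <- s * sup_frac[i, 1] * spec$half_width
      z <- sup_frac[i, 2] * spec$half_depth
      y <- phantom_height(spec, x, z, phases) + h2
      sup[[length(sup) + 1]] <- region_spec(
        c(x, y, z), size = patch_size,
        label = sprintf("SUP-%s-%d", if (s > 0) "right" else "left", i))
    }
  }
  list(mesh = mesh, measurement = meas, superimposition = sup, spec = spec)
}

# signed volume by the divergence theorem; positive for outward orientation
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c2 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c2[, 3] - b[, 3] * c2[, 2]) -
      a[, 2] * (b[, 1] * c2[, 3] - b[, 3] * c2[, 1]) +
      a[, 3] * (b[, 1] * c2[, 2] - b[, 2] * c2[, 1])) / 6
}

#' Acquisition specification for the scan simulator
#'
#' Parameters mirror the acquisition settings that matter for surface
#' recovery: voxel spacing (anisotropy allowed), a Gaussian point-spread
#' blur standing in for partial-volume averaging, additive Gaussian noise on
#' grey values whose standard deviation scales as `1/sqrt(exposure time)`
#' (so halving the exposure, as in an ultra-low-dose protocol, raises noise
#' by sqrt(2)), nominal bone and water grey values, and a sub-voxel grid
#' offset.
#'
#' @param voxel_mm length-3 voxel spacing, mm.
#' @param psf_sigma_mm Gaussian blur sigma, mm.
#' @param noise_sd_ref noise standard deviation (grey values) at the
#'   reference exposure.
#' @param exposure_ref_s,exposure_s reference and actual exposure times (s).
#' @param bone_value,water_value nominal grey values.
#' @param value_range representable grey range.
#' @param grid_offset_frac length-3 sub-voxel origin shift, in voxels.
#' @param seed integer seed for the noise draw.
#' @param label optional setting label carried into result tables.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(voxel_mm, psf_sigma_mm = 0.3, noise_sd_ref = 50,
                             exposure_ref_s = 12, exposure_s = 12,
                             bone_value = 1200, water_value = 0,
                             value_range = c(-1000, 3095),
                             grid_offset_frac = c(0, 0, 0), seed = 1L,
                             label = NULL) {
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  stopifnot(all(voxel_mm > 0), psf_sigma_mm >= 0, noise_sd_ref >= 0,
            exposure_s > 0)
  structure(list(voxel_mm = voxel_mm, psf_sigma_mm = psf_sigma_mm,
                 noise_sd_ref = noise_sd_ref, exposure_ref_s = exposure_ref_s,
                 exposure_s = exposure_s, bone_value = bone_value,
                 water_value = water_value, value_range = value_range,
                 grid_offset_frac = as.numeric(grid_offset_frac),
                 seed = as.integer(seed), label = label),
            class = "acquisition_spec")
}

#' @rdname acquisition_spec
#' @param preset one of `"ct"` (0.625 mm slices, anisotropic), `"cbct_0.3"`
#'   (0.3 mm isotropic, 4 s), `"cbct_0.2"` (0.2 mm isotropic, regular 12 s
#'   dose) or `"cbct_0.2_lowdose"` (0.2 mm isotropic, 6 s ultra-low dose).
#' @param noise multiply the preset's noise by this factor (0 for noiseless
#'   runs).
#' @param ... further arguments passed to `acquisition_spec()` (e.g.
#'   `grid_offset_frac`).
#' @export
acquisition_preset <- function(preset = c("ct", "cbct_0.3", "cbct_0.2",
                                          "cbct_0.2_lowdose"),
                               noise = 1, seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    ct = acquisition_spec(c(0.55, 0.55, 0.625), psf_sigma_mm = 0.5,
                          noise_sd_ref = 15, exposure_ref_s = 1,
                          exposure_s = 1, label = "ct", seed = seed, ...),
    cbct_0.3 = acquisition_spec(c(0.3, 0.3, 0.3), psf_sigma_mm = 0.3,
                                noise_sd_ref = 40, exposure_ref_s = 4,
                                exposure_s = 4, label = "cbct_0.3",
                                seed = seed, ...),
    cbct_0.2 = acquisition_spec(c(0.2, 0.2, 0.2), psf_sigma_mm = 0.25,
                                noise_sd_ref = 50, exposure_ref_s = 12,
                                exposure_s = 12, label = "cbct_0.2",
                                seed = seed, ...),
    cbct_0.2_lowdose = acquisition_spec(c(0.2, 0.2, 0.2), psf_sigma_mm = 0.25,
                                        noise_sd_ref = 50, exposure_ref_s = 12,
                                        exposure_s = 6,
                                        label = "cbct_0.2_lowdose",
                                        seed = seed, ...))
  base$noise_sd_ref <- base$noise_sd_ref * noise
  base
}

#' Effective noise level of an acquisition
#'
#' @param acq an [acquisition_spec()].
#' @return the noise standard deviation after exposure-time scaling.
#' @export
acquisition_noise_sd <- function(acq) {
  acq$noise_sd_ref * sqrt(acq$exposure_ref_s / acq$exposure_s)
}

#' Simulate a tomographic scan of a surface model
#'
#' Rasterizes the closed `truth` mesh to a binary interior occupancy on the
#' acquisition grid (exact parity voxelization at voxel centres), maps
#' occupancy to grey values (bone inside, water outside), applies the
#' Gaussian point-spread blur, and adds exposure-scaled Gaussian noise.
#' Deterministic for a fixed `acq$seed`.
#'
#' @param truth a closed [tri_mesh()] (the ground-truth surface).
#' @param acq an [acquisition_spec()].
#' @param padding_mm margin added around the mesh bounding box.
#' @return a [scan_volume()].
#' @export
voxelize <- function(truth, acq, padding_mm = NULL) {
  if (is.null(padding_mm)) padding_mm <- 3 * acq$psf_sigma_mm + 2 * max(acq$voxel_mm)
  bb <- apply(truth$vertices, 2, range)
  origin <- bb[1, ] - padding_mm + acq$grid_offset_frac * acq$voxel_mm
  dims <- as.integer(ceiling((bb[2, ] + padding_mm - origin) / acq$voxel_mm)) + 1L
  occ <- cpp_voxelize_parity(truth$vertices, truth$faces, origin, acq$voxel_mm,
                             dims)
  vals <- acq$water_value + (acq$bone_value - acq$water_value) * occ
  if (acq$psf_sigma_mm > 0) {
    vals <- cpp_gaussian_blur(vals, dims[1], dims[2], dims[3],
                              acq$psf_sigma_mm / acq$voxel_mm)
  }
  sd <- acquisition_noise_sd(acq)
  if (sd > 0) {
    vals <- vals + with_seed(acq$seed, rnorm(length(vals), sd = sd))
  }
  vr <- range(acq$value_range, vals)
  scan_volume(array(vals, dims), acq$voxel_mm, origin, value_range = vr)
}

#' Operator threshold variability
#'
#' Emulates the repeated visual choice of a single segmentation threshold:
#' each session's threshold is the nominal bone/water midpoint plus Gaussian
#' jitter. The default jitter standard deviation (22.5 grey values) is
#' calibrated so the median absolute difference between two repeated choices
#' is about 21.5 grey values on a CT-like grey range.
#'
#' @param jitter_sd standard deviation of the threshold jitter (grey values).
#' @param seed integer seed.
#' @return object of class `operator_spec`.
#' @export
operator_spec <- function(jitter_sd = 22.5, seed = 1L) {
  stopifnot(is.finite(jitter_sd), jitter_sd >= 0)
  structure(list(jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "operator_spec")
}

#' Simulate repeated segmentation sessions of one scan
#'
#' Scans the truth once, then draws `n_repeats` thresholds around the
#' nominal bone/water midpoint from the operator's jitter distribution: the
#' same volume segmented at different thresholds, as in repeated visual
#' segmentation of one tomographic dataset.
#'
#' @param truth a closed [tri_mesh()].
#' @param acq an [acquisition_spec()].
#' @param operator an [operator_spec()].
#' @param n_repeats number of segmentation sessions.
#' @return list with `volume` (a [scan_volume()]), `nominal` threshold,
#'   `thresholds` (length `n_repeats`), and the seeds used.
#' @export
simulate_session <- function(truth, acq, operator = operator_spec(),
                             n_repeats = 2) {
  vol <- voxelize(truth, acq)
  nominal <- (acq$bone_value + acq$water_value) / 2
  thresholds <- nominal +
    with_seed(operator$seed, rnorm(n_repeats, sd = operator$jitter_sd))
  list(volume = vol, nominal = nominal, thresholds = thresholds,
       seeds = list(acquisition = acq$seed, operator = operator$seed))
}
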