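# Orchestration of the two studies: three-level reproducibility of repeated
# segmentations, and trueness of segmented models against a ground-truth
# reference surface.

#' Three-level reproducibility assessment of one segmentation pair
#'
#' Compares two surface models segmented from the same volume: (1) MAD/SDAD
#' at the measurement areas with both models in their original volume frame;
#' (2) point-to-plane ICP on the superimposition areas, decomposed into six
#' axis-wise motions; (3) MAD/SDAD after superimposition. Perfect
#' reproducibility is zero MAD before superimposition and zero
#' movements/rotations during it.
#'
#' @param mesh_a,mesh_b the two segmentations (same frame); `mesh_a` is the
#'   moving/source model.
#' @param measurement list of [region_spec()]s for the measurement areas.
#' @param superimposition list of [region_spec()]s for the ICP reference
#'   areas.
#' @param settings an [icp_settings()].
#' @return list with `pre` and `post` ([mad_sdad()] results), `motion`
#'   (six-component decomposition), `transform`, and the ICP `trace`.
#' @export
assess_reproducibility_pair <- function(mesh_a, mesh_b, measurement,
                                        superimposition,
                                        settings = icp_settings()) {
  idx <- mesh_index(mesh_a)
  adj <- face_adjacency(mesh_a)
  meas <- lapply(measurement, function(s)
    grow_patch(mesh_a, s, index = idx, adjacency = adj))
  sup <- lapply(superimposition, function(s)
    grow_patch(mesh_a, s, index = idx, adjacency = adj))

  pre <- mad_sdad(distance_field(mesh_a, mesh_b, meas))
  reg <- icp_register(mesh_a, mesh_b, reference = sup, settings = settings)
  motion <- decompose_transform(reg$transform)
  moved <- transform_mesh(mesh_a, reg$transform)
  post <- mad_sdad(distance_field(moved, mesh_b, meas))
  list(pre = pre, post = post, motion = motion, transform = reg$transform,
       trace = reg$trace)
}

#' Trueness assessment of one segmented model against its reference
#'
#' Superimposes the segmented (test) model onto the reference surface by
#' point-to-plane ICP on the superimposition areas, then measures MAD/SDAD
#' from the registered test model's vertices to the reference surface at the
#' eight measurement areas (patches grown on the registered test model
#' around seeds defined on the reference).
#'
#' @param test the segmented [tri_mesh()].
#' @param reference the ground-truth [tri_mesh()].
#' @param measurement,superimposition lists of [region_spec()]s (seed
#'   coordinates in the reference frame).
#' @param settings an [icp_settings()].
#' @param map_path if non-NULL, export the distance map there (PLY + CSV).
#' @return list with `result` ([mad_sdad()]), `motion`, `transform`, `trace`.
#' @export
assess_trueness <- function(test, reference, measurement, superimposition,
                            settings = icp_settings(), map_path = NULL) {
  idx <- mesh_index(test)
  adj <- face_adjacency(test)
  sup <- lapply(superimposition, function(s)
    grow_patch(test, s, index = idx, adjacency = adj))
  reg <- icp_register(test, reference, reference = sup, settings = settings)
  moved <- transform_mesh(test, reg$transform)

  idx2 <- mesh_index(moved)
  adj2 <- adj  # topology unchanged by a rigid move
  meas <- lapply(measurement, function(s)
    grow_patch(moved, s, index = idx2, adjacency = adj2))
  field <- distance_field(moved, reference, meas)
  if (!is.null(map_path)) export_distance_map(field, moved, map_path)
  list(result = mad_sdad(field), motion = decompose_transform(reg$transform),
       transform = reg$transform, trace = reg$trace)
}

outcome_rows <- function(specimen, setting, values) {
  data.frame(specimen = specimen, setting = setting,
             outcome = names(values), value = as.numeric(values),
             row.names = NULL)
}

#' Run the reproducibility study over a manifest of cases
#'
#' Each case holds one scan of one specimen under one acquisition setting,
#' with two (or more) recorded segmentation thresholds. Consecutive repeats
#' are segmented and compared pairwise at the three assessment levels.
#'
#' @param cases list; each element a list with `specimen`, `setting`,
#'   `volume` (a [scan_volume()]), `thresholds` (numeric, length >= 2),
#'   `measurement` and `superimposition` (lists of [region_spec()]).
#' @param settings an [icp_settings()].
#' @return a tidy outcome table (data.frame: specimen, setting, outcome,
#'   value) with outcomes `threshold_diff`, `mad_pre`, `sdad_pre`, `tx`,
#'   `ty`, `tz`, `rx`, `ry`, `rz`, `mad_post`, `sdad_post`.
#' @export
run_reproducibility <- function(cases, settings = icp_settings()) {
  out <- lapply(cases, function(cs) {
    meshes <- lapply(cs$thresholds, function(t)
      extract_isosurface(cs$volume, t))
    rows <- list()
    for (i in seq_len(length(meshes) - 1)) {
      a <- assess_reproducibility_pair(meshes[[i]], meshes[[i + 1]],
                                       cs$measurement, cs$superimposition,
                                       settings = settings)
      m <- a$motion
      rows[[i]] <- outcome_rows(cs$specimen, cs$setting, c(
        threshold_diff = cs$thresholds[i + 1] - cs$thresholds[i],
        mad_pre = a$pre$mad, sdad_pre = a$pre$sdad,
        tx = m$tx, ty = m$ty, tz = m$tz, rx = m$rx, ry = m$ry, rz = m$rz,
        mad_post = a$post$mad, sdad_post = a$post$sdad))
    }
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Run the trueness study over a manifest of cases
#'
#' @param cases list; each element a list with `specimen`, `setting`,
#'   `volume`, `threshold` (single), `reference` (ground-truth
#'   [tri_mesh()]), `measurement`, `superimposition`; optionally `map_path`.
#' @param settings an [icp_settings()].
#' @return tidy outcome table with outcomes `trueness_mad`, `trueness_sdad`
#'   and the six registration motion components.
#' @export
run_trueness <- function(cases, settings = icp_settings()) {
  out <- lapply(cases, function(cs) {
    test <- extract_isosurface(cs$volume, cs$threshold)
    a <- assess_trueness(test, cs$reference, cs$measurement,
                         cs$superimposition, settings = settings,
                         map_path = cs$map_path)
    m <- a$motion
    outcome_rows(cs$specimen, cs$setting, c(
      trueness_mad = a$result$mad, trueness_sdad = a$result$sdad,
      tx = m$tx, ty = m$ty, tz = m$tz, rx = m$rx, ry = m$ry, rz = m$rz))
  })
  do.call(rbind, out)
}

#' End-to-end synthetic demonstration study
#'
#' Generates `n_phantoms` ground-truth shells, scans each under the four
#' acquisition presets, simulates `n_repeats` threshold-segmentation
#' sessions per scan, and runs both the reproducibility and the trueness
#' studies. All randomness derives from `seed`; re-running with the same
#' seed reproduces every outcome value exactly.
#'
#' @param seed master integer seed.
#' @param n_phantoms number of synthetic specimens.
#' @param presets acquisition preset names (see [acquisition_preset()]).
#' @param n_repeats segmentation sessions per scan.
#' @param noise noise multiplier passed to the presets (0 for noiseless).
#' @param jitter_sd operator threshold jitter (grey values).
#' @param n_rings,n_around truth-mesh resolution (see [make_phantom()]).
#' @param patch_size triangles per measurement/superimposition area.
#' @param settings an [icp_settings()].
#' @param out_dir if non-NULL, writes the outcome tables (CSV) and a run
#'   log (JSON, requires jsonlite) there.
#' @return list with `reproducibility` and `trueness` outcome tables,
#'   `summary` (medians/IQRs per setting), and `manifest` metadata.
#' @export
run_demo <- function(seed = 1, n_phantoms = 4,
                     presets = c("ct", "cbct_0.3", "cbct_0.2",
                                 "cbct_0.2_lowdose"),
                     n_repeats = 2, noise = 1, jitter_sd = 22.5,
                     n_rings = 44, n_around = 150, patch_size = 1000,
                     settings = icp_settings(), out_dir = NULL) {
  seed <- as.integer(seed)
  repro_cases <- list()
  true_cases <- list()
  manifest <- list()
  for (ph in seq_len(n_phantoms)) {
    phantom <- make_phantom(phantom_spec(seed = seed + 1000L * ph),
                            n_rings = n_rings, n_around = n_around,
                            patch_size = patch_size)
    for (pi in seq_along(presets)) {
      case_seed <- seed + 1000L * ph + pi
      acq <- acquisition_preset(presets[pi], noise = noise, seed = case_seed)
      sess <- simulate_session(phantom$mesh, acq,
                               operator_spec(jitter_sd = jitter_sd,
                                             seed = case_seed + 500L),
                               n_repeats = n_repeats)
      specimen <- sprintf("phantom%02d", ph)
      repro_cases[[length(repro_cases) + 1]] <- list(
        specimen = specimen, setting = acq$label, volume = sess$volume,
        thresholds = sess$thresholds,
        measurement = phantom$measurement,
        superimposition = phantom$superimposition)
      true_cases[[length(true_cases) + 1]] <- list(
        specimen = specimen, setting = acq$label, volume = sess$volume,
        threshold = sess$thresholds[1], reference = phantom$mesh,
        measurement = phantom$measurement,
        superimposition = phantom$superimposition, map_path = NULL)
      manifest[[length(manifest) + 1]] <- list(
        specimen = specimen, setting = acq$label, seed = case_seed,
        thresholds = sess$thresholds, nominal = sess$nominal,
        voxel_mm = acq$voxel_mm, noise_sd = acquisition_noise_sd(acq))
    }
  }
  repro <- run_reproducibility(repro_cases, settings = settings)
  true_tab <- run_trueness(true_cases, settings = settings)
  summary <- rbind(summarize_outcomes(repro), summarize_outcomes(true_tab))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(repro, file.path(out_dir, "reproducibility.csv"),
                     row.names = FALSE)
    utils::write.csv(true_tab, file.path(out_dir, "trueness.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(list(seed = seed, cases = manifest),
                           file.path(out_dir, "run_log.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  list(reproducibility = repro, trueness = true_tab, summary = summary,
       manifest = manifest)
}
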