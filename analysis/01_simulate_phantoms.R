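#!/usr/bin/env Rscript
# Step 1 — simulate the study materials.
#
# Builds four synthetic thin-shell "specimens" (the ground-truth surfaces a
# high-accuracy optical scan would provide), scans each under the four
# acquisition presets (CT 0.625 mm anisotropic; CBCT 0.3 mm; CBCT 0.2 mm
# regular dose; CBCT 0.2 mm ultra-low dose), and draws two operator
# thresholds per scan. Everything is persisted so the later steps can be
# re-run in isolation: truth meshes as STL, volumes as NRRD, region seeds
# and session thresholds as JSON.

library(surfaccuracy)
library(jsonlite)

SEED <- 1L
N_PHANTOMS <- 4
PRESETS <- c("ct", "cbct_0.3", "cbct_0.2", "cbct_0.2_lowdose")

fix_dir <- "results/fixtures"
dir.create(fix_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- list(seed = SEED, cases = list())
for (ph in seq_len(N_PHANTOMS)) {
  phantom <- make_phantom(phantom_spec(seed = SEED + 1000L * ph))
  specimen <- sprintf("phantom%02d", ph)
  write_mesh(phantom$mesh, file.path(fix_dir, paste0(specimen, "_truth.stl")))
  regions <- list(
    measurement = lapply(phantom$measurement, function(s)
      list(seed = s$seed, size = s$size, label = s$label)),
    superimposition = lapply(phantom$superimposition, function(s)
      list(seed = s$seed, size = s$size, label = s$label)))
  write_json(regions, file.path(fix_dir, paste0(specimen, "_regions.json")),
             auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d vertices, %d faces, area %.0f mm^2\n", specimen,
              nrow(phantom$mesh$vertices), nrow(phantom$mesh$faces),
              sum(face_areas(phantom$mesh))))

  for (pi in seq_along(PRESETS)) {
    case_seed <- SEED + 1000L * ph + pi
    acq <- acquisition_preset(PRESETS[pi], seed = case_seed)
    sess <- simulate_session(phantom$mesh, acq,
                             operator_spec(seed = case_seed + 500L), 2)
    vol_file <- sprintf("%s_%s.nrrd", specimen, acq$label)
    write_volume(sess$volume, file.path(fix_dir, vol_file))
    manifest$cases[[length(manifest$cases) + 1]] <- list(
      specimen = specimen, setting = acq$label, volume = vol_file,
      truth = paste0(specimen, "_truth.stl"),
      regions = paste0(specimen, "_regions.json"),
      nominal_threshold = sess$nominal, thresholds = sess$thresholds,
      voxel_mm = acq$voxel_mm, noise_sd = acquisition_noise_sd(acq))
    cat(sprintf("  %-18s grid %s, noise sd %.1f, thresholds %.1f / %.1f\n",
                acq$label, paste(dim(sess$volume$values), collapse = "x"),
                acquisition_noise_sd(acq), sess$thresholds[1],
                sess$thresholds[2]))
  }
}
write_json(manifest, file.path(fix_dir, "manifest.json"),
           auto_unbox = TRUE, digits = NA)
cat("Wrote", length(manifest$cases), "cases to", fix_dir, "\n")
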