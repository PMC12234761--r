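#!/usr/bin/env Rscript
# Step 3 — trueness of the segmented models against the ground truth.
#
# The first-session segmentation of each scan is superimposed onto its
# ground-truth surface (point-to-plane ICP on the superimposition areas) and
# MAD/SDAD are measured at the eight measurement areas. Per-vertex distance
# maps are exported for the best and worst case.

library(surfaccuracy)
library(jsonlite)

fix_dir <- "results/fixtures"
if (!file.exists(file.path(fix_dir, "manifest.json")))
  stop("run analysis/01_simulate_phantoms.R first")
manifest <- read_json(file.path(fix_dir, "manifest.json"))

load_regions <- function(path) {
  r <- read_json(file.path(fix_dir, path))
  lapply(r, function(set) lapply(set, function(s)
    region_spec(unlist(s$seed), size = s$size, label = s$label)))
}

cases <- lapply(manifest$cases, function(cs) {
  regions <- load_regions(cs$regions)
  list(specimen = cs$specimen, setting = cs$setting,
       volume = read_volume(file.path(fix_dir, cs$volume)),
       threshold = unlist(cs$thresholds)[1],
       reference = read_mesh(file.path(fix_dir, cs$truth), weld = TRUE),
       measurement = regions$measurement,
       superimposition = regions$superimposition,
       map_path = NULL)
})

tab <- run_trueness(cases)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/trueness.csv", row.names = FALSE)

mad <- tab[tab$outcome == "trueness_mad", ]
cat("Trueness MAD (mm) by acquisition setting:\n")
for (s in unique(mad$setting))
  cat(sprintf("  %-18s median %.4f  IQR %.4f\n", s,
              median(mad$value[mad$setting == s]),
              diff(quantile(mad$value[mad$setting == s], c(0.25, 0.75)))))
cat(sprintf("Overall: median %.4f  IQR %.4f mm\n",
            median(mad$value), diff(quantile(mad$value, c(0.25, 0.75)))))

# distance maps for the extreme cases
map_dir <- "results/distance_maps"
dir.create(map_dir, showWarnings = FALSE)
for (pick in c(which.min(mad$value), which.max(mad$value))) {
  cs <- cases[[which(vapply(cases, function(x)
    x$specimen == mad$specimen[pick] && x$setting == mad$setting[pick],
    logical(1)))[1]]]
  test <- extract_isosurface(cs$volume, cs$threshold)
  assess_trueness(test, cs$reference, cs$measurement, cs$superimposition,
                  map_path = file.path(map_dir,
                    sprintf("%s_%s.ply", cs$specimen, cs$setting)))
}
cat("Distance maps written to", map_dir, "\n")
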