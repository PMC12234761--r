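# surfaccuracy

Quantifies how faithfully 3D bone surface models segmented from CT and CBCT
volumes represent the true skeletal surface, and how reproducible repeated
single-threshold segmentations are. The motivating application is the
anterior cranial base — a thin skeletal structure used as the reference
area for craniofacial superimposition — where accuracy at the 0.1 mm scale
decides whether lower-radiation imaging protocols are good enough for
morphometric work.

The package is aimed at researchers validating imaging/segmentation
protocols: it implements the full measurement chain (segmentation →
superimposition → surface-distance metrics → nonparametric statistics)
plus a synthetic phantom study that exercises every stage against known
ground truth, since real skull scans are typically confidential.

## What it computes

* **Segmentation** — `extract_isosurface(volume, t)` triangulates the
  grey-value level set `{v = t}` with a marching-cubes variant (six-fold
  tetrahedral cell decomposition, linear interpolation along edges), in
  physical millimetres, with no smoothing.
* **Superimposition** — `icp_register(moving, fixed, reference)` performs
  rigid point-to-plane ICP restricted to reference areas, minimizing
  `Σ[(R·p + t − q)·n_q]²` over exact closest-point correspondences
  (defaults: 100% overlap, 100% sampling, 50 iterations).
  `decompose_transform()` reports the best-fit motion as
  `(tx, ty, tz)` mm and `(rx, ry, rz)` degrees (extrinsic XYZ; X lateral,
  Y vertical, Z anteroposterior).
* **Metrics** — `grow_patch()` builds circular measurement areas of a
  fixed triangle count (default 1000) around seed points;
  `distance_field()` takes each source vertex to its exact closest point
  on the target surface; `mad_sdad()` pools the absolute distances into
  the mean absolute distance (MAD) and its standard deviation (SDAD);
  `export_distance_map()` writes per-vertex distance maps (PLY + CSV).
* **Study drivers** — `run_reproducibility()` (three-level assessment of
  repeated segmentations: MAD/SDAD in the original frame, best-fit
  motions, MAD/SDAD after superimposition), `run_trueness()` (segmented
  model vs reference surface), `run_demo()` (the full synthetic study).
* **Statistics** — `wilcoxon_signed_rank()`, `kruskal_wallis()`,
  `mann_whitney_u()` (exact enumeration for small samples, tie-corrected
  approximations otherwise), `summarize_outcomes()` (median/IQR with
  Shapiro–Wilk normality flags).

## Worked example

```r
library(surfaccuracy)

# a synthetic specimen: ground-truth shell + measurement/superimposition seeds
phantom <- make_phantom(phantom_spec(seed = 7))

# scan it like a 0.3 mm CBCT and segment at the bone/water midpoint
acq  <- acquisition_preset("cbct_0.3", seed = 3)
vol  <- voxelize(phantom$mesh, acq)
mesh <- extract_isosurface(vol, 600)

# trueness: register onto the truth, measure MAD/SDAD at the eight areas
res <- assess_trueness(mesh, phantom$mesh,
                       phantom$measurement, phantom$superimposition)
res$result
#> MAD 0.022318 mm, SDAD 0.017151 mm over 4429 vertices in 8 region(s)
round(unlist(res$motion), 4)
#>      tx      ty      tz      rx      ry      rz
#>  0.0044 -0.0074  0.0536 -0.1800  0.0909  0.0289
```

A 0.3 mm CBCT-like scan with realistic noise reproduces the true surface to
a mean absolute distance of ~0.02 mm at the measurement areas, and the
best-fit superimposition moves the model by less than 0.2 mm/degrees on
every axis — i.e. segmentation at this resolution is not the limiting error
source. The full study over 4 phantoms × 4 acquisition presets × 2
segmentation sessions is driven by the numbered scripts:

```sh
Rscript analysis/01_simulate_phantoms.R   # specimens, volumes, thresholds
Rscript analysis/02_reproducibility.R     # three-level repeat comparison
Rscript analysis/03_trueness.R            # segmented vs truth + distance maps
Rscript analysis/04_statistics.R          # medians/IQRs, KW/MWU/Wilcoxon
```

Each step persists its inputs and outputs under `results/` (volumes as
NRRD, meshes as STL, tables as CSV), so any stage can be re-run in
isolation.

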