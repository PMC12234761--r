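---
title: "Assessing trueness and reproducibility of segmented bone surface models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing trueness and reproducibility of segmented bone surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Surface models of thin skeletal structures — the anterior cranial base is
the motivating case — are routinely segmented from CT and CBCT volumes by
choosing a single grey-value threshold and triangulating its isosurface.
Two questions decide whether such models are fit for morphometric use:

* **Reproducibility (precision)**: how much do models differ when the same
  volume is segmented repeatedly, with the threshold chosen visually each
  time?
* **Trueness**: how far is a segmented model from the actual bone surface,
  represented by a high-accuracy reference scan?

Both are quantified here by the **mean absolute distance (MAD)**: sample
the vertices of one mesh inside predefined measurement areas, take for each
the unsigned distance to the *exact closest point* on the other mesh
(triangle interiors, edges and vertices all considered — not
vertex-to-vertex, which would inflate distances on coarse meshes), and
average. The **SDAD** is the standard deviation of those absolute
distances, with the population denominator *n* (immaterial at thousands of
vertices; fixed for exactness). Distances from all measurement areas are
pooled into one variable; per-area values are kept for diagnostics.

MAD is directional: `MAD(A -> B) != MAD(B -> A)` in general. The package
fixes the direction as *test model -> reference surface* for trueness and
*first segmentation -> second segmentation* for reproducibility, and the
tests document the asymmetry on a coarse-vs-fine mesh pair.

## Segmentation

`extract_isosurface()` triangulates the level set `{value = t}` with a
marching-cubes variant: each voxel cell is decomposed into six tetrahedra
(the Kuhn triangulation around the cell's main diagonal) and crossings are
linearly interpolated along tetrahedron edges. We chose this variant over
the classical 256-entry cube table because it is ambiguity-free by
construction — the decomposition is translation-consistent, so shared cell
faces triangulate identically in neighbouring cells and the mesh is
watertight away from the volume boundary — while having the same
sub-half-voxel accuracy, which is what matters at the 0.1 mm scale of
interest. Linear interpolation (not edge midpoints) is essential: it is
what makes trueness converge roughly quadratically on smooth fields, and at
0.2 mm voxels puts discretization error near 0.01 mm. No smoothing or
decimation is applied afterwards; vertex counts therefore track voxel
resolution, as raw segmentations do.

The isosurface bounds the region `value >= t` (the "outer" bone boundary),
with normals pointing out of bone. `suggest_threshold()` provides a
deterministic stand-in for the visual threshold choice (Otsu's
between-class variance over a histogram, returning the centre of the
maximal plateau so empty valleys between sharp modes resolve to their
midpoint); the study pipeline, however, treats thresholds as *inputs*,
because operator threshold variability is one of the quantities under
study.

## Superimposition

`icp_register()` implements rigid point-to-plane ICP with the protocol
fixed throughout the study: 100% estimated overlap, 100% point sampling,
exact nearest-neighbour correspondence, 50 iterations. Each iteration
matches the reference-area vertices of the moving mesh to their exact
closest points on the fixed surface (an axis-aligned bounding-box tree
prunes the search but never approximates it) and minimizes
`sum(((R p + t - q) . n_q)^2)` by the standard small-angle linearization, a
6x6 least-squares system whose rotation increment is re-orthonormalized
through the exact axis-angle exponential. Iteration stops early only when
the relative objective change falls below 1e-10 — far below numerical
noise, so the nominal 50 iterations are effectively honoured. With overlap
below 1 the worst-matching fraction of correspondences is discarded each
iteration (trimmed ICP, the usual reading of "estimated overlap"); point
sampling below 1 draws a seeded uniform vertex subsample once, for
reproducibility.

Initialization is the identity: in this workflow the two meshes either
share the tomographic volume frame (reproducibility) or are compared after
segmentation in the same physical frame (trueness), so no global
pre-alignment is appropriate. A full-mesh centroid translation is available
as an option. On the synthetic phantom the basin of attraction comfortably
covers perturbations of 10 degrees / 3 mm, recovered to better than
0.01 mm / 0.01 degree.

The best-fit motion is reported as six axis-wise components via
`decompose_transform()`. The Euler convention had to be fixed by us (the
craniofacial reporting convention names axes but not an order): extrinsic
X-then-Y-then-Z, angles in degrees, translations in the fixed mesh's frame,
with X lateral, Y vertical, Z anteroposterior. Recomposition reproduces the
transform to 1e-9 below gimbal lock; at `|ry| ~ 90` degrees the
decomposition refuses and reports the quaternion instead.

Measurement and superimposition areas are circular patches of a fixed
triangle count (default 1000), grown face-by-face from a seed in order of
centroid distance to the seed (a geodesic approximation; exact geodesics
would change patch membership only at the rim). Ties break on face index,
so patches are deterministic. Because the triangle count is fixed, the
physical patch size varies with mesh resolution — intentional, as it
mirrors how such areas are defined in segmentation software.

## The synthetic study

Real skull scans cannot be redistributed, so the package ships a generator
whose defaults define the study conditions:

* **Phantom** (`make_phantom()`): a closed shell of default thickness
  1.5 mm — thin, as the anterior cranial base is — shaped as an elliptic
  paraboloid bowl (32 x 24 mm footprint, 6 mm depth) with sinusoidal
  ridges (0.8 mm amplitude), bilaterally symmetric like the anatomy, with
  the ridge phase randomized anteroposteriorly per specimen. Eight
  measurement seeds sit in mirrored pairs on the upper surface; ten
  superimposition seeds are spread evenly across it.
* **Acquisition** (`acquisition_preset()`): exact parity voxelization of
  the shell interior at the preset's voxel size, bone at grey value 1200
  over water at 0, Gaussian point-spread blur as the partial-volume
  stand-in, and additive Gaussian grey-value noise scaled by
  `1/sqrt(exposure time)` so the ultra-low-dose protocol (6 s vs 12 s)
  carries `sqrt(2)` more noise. The four presets mirror a clinical CT
  (0.55 x 0.55 x 0.625 mm, low noise), a 0.3 mm CBCT at 4 s, and a 0.2 mm
  CBCT at regular (12 s) and halved exposure. Blur sigmas (0.5 / 0.3 /
  0.25 mm) were chosen once as plausible scanner point-spread widths at
  those resolutions.
* **Operator** (`operator_spec()`): repeated threshold choices jitter
  around the bone/water midpoint with standard deviation 22.5 grey values,
  calibrated so the median absolute difference between two repeated
  choices is about 21.5 grey values — the magnitude reported for repeated
  visual thresholding on CT-like grey ranges.

What the phantom does *not* emulate: CBCT grey-value inhomogeneity across
the field of view, scatter and beam hardening, metal or motion artifacts,
and real trabecular texture. Passing the synthetic study therefore
validates the *pipeline* — segmentation, registration and metrics at known
ground truth — not any claim about a particular scanner's image quality.

## Numerical choices and degenerate inputs

* Closest-point queries are exact; ties between faces resolve to the lower
  face index.
* `weld_vertices()` merges coincident STL corners on a 1e-6 mm grid;
  welding is **off** by default on read, since whether segmentation
  software welds before measuring is generally unknown and the metrics are
  defined per stored vertex.
* The linearized ICP step solves rank-deficient systems (e.g. purely
  planar normals) in the minimum-norm sense, which turns a pure plane
  offset into a pure translation; `icp_register()` refuses such reference
  geometry outright with a rank-deficiency error, since a registration
  with unconstrained degrees of freedom is meaningless.
* Volumes must carry voxel spacing; there is no silent default. Anisotropic
  spacing flows through marching tetrahedra directly — volumes are never
  resampled to isotropic grids, which would add an uncontrolled error term.
* Rank tests: zero differences are dropped from the signed-rank test;
  exact enumeration (valid under ties) is used up to n = 12 (signed-rank)
  or 20000 arrangements (Mann-Whitney, Kruskal-Wallis with small pooled
  n), tie-corrected normal/chi-square approximations with continuity
  correction beyond. Quartiles are type-7 (linear interpolation); IQR
  conventions differ across software, so this is part of the contract.

## Problem sizes

The shipped study (`run_demo()`, also driven by the `analysis/` scripts
and `scripts/acceptance.R`) uses four phantoms by four presets with two
segmentation sessions each. Truth meshes carry about 26 000 faces
(44 rings x 150 spokes per sheet); segmented models range from about
38 000 faces (CT) to 340 000 faces (0.2 mm CBCT), comparable in density to
real segmentations at those voxel sizes. Unit tests use a coarser phantom
(26 x 90, 400-triangle patches) — the properties under test are
scale-free.

## Known limitations

* The geodesic-approximating patch growth can differ from true geodesic
  discs on strongly curved or slitted surfaces.
* Marching tetrahedra produce more, thinner triangles than cube-table
  marching for the same grid; metrics are unaffected, but face counts are
  not comparable to cube-table implementations.
* ICP convergence is only locally guaranteed; the monotone-objective check
  in the tests is an empirical property of these well-posed problems, not
  a theorem of the point-to-plane variant.
* DICOM series input is not supported; convert to NIfTI or NRRD first.
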