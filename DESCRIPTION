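Package: surfaccuracy
Title: Accuracy Assessment of Bone Surface Models Segmented from CT and CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the trueness and reproducibility of
    three-dimensional bone surface models segmented from computed tomography
    (CT) and cone beam computed tomography (CBCT) volumes. Provides
    single-threshold isosurface segmentation (a marching-cubes variant),
    rigid point-to-plane iterative closest point (ICP) superimposition
    restricted to reference areas, regional surface-distance metrics (mean
    absolute distance, MAD, and the standard deviation of absolute distances,
    SDAD), decomposition of best-fit motions into six axis-wise components,
    per-vertex distance-map export, a synthetic thin-shell phantom and
    CT/CBCT acquisition simulator for validation without confidential scan
    data, and a nonparametric comparison battery (Wilcoxon signed-rank,
    Kruskal-Wallis, Mann-Whitney U with Bonferroni adjustment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    igraph
Config/testthat/edition: 3
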