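# hepamorph

3D morphometric analysis of hepatic fibrosis in whole-liver bright-field
(Nissl) volumes, for researchers quantifying vascular remodelling and
steatosis in serial-section block-face microscopy of the mouse liver.  In
these volumes vessel and sinusoid lumens image bright, parenchyma dark, and
vacuolated steatotic regions in between; hepamorph turns that contrast into
the standard fibrosis read-outs:

* **Vessel trees** — seeded region growing of central/portal veins,
  companion-proximity classification of vein type (portal veins travel with
  artery and bile duct; central veins travel alone), and the four-parameter
  morphometry panel from a topology-preserving 3D skeleton with
  EDT-coded diameters:

  - mean diameter *d̄* = arc-length-weighted mean of per-point diameters
    (diameter = 2 × Euclidean distance transform at the centreline),
  - length density *L_V = L / V_ref* (reported in m·mm⁻³),
  - number of segments (branch-graph edge count),
  - volume fraction *V_V = V / V_ref*.

* **Sinusoids** — thresholding with vessel subtraction and a
  minimum-component-volume filter, then the same panel.
* **Steatosis** — a trainable voxel classifier (multi-scale features +
  regularized logistic model with quadratic expansion) standing in for
  cloud deep-learning semantic segmentation, with loss/accuracy/IoU
  training curves, morphological post-processing, and mask × gray
  extraction.
* **Perivascular statistics** — steatotic percentage per 30-µm distance
  band from the central-vein surface (half-open bands on the exterior
  Euclidean distance field), 150-µm shells around individual branches
  stratified by branch diameter, and label-analysis-style per-component shape
  descriptors (Volume3d, EqDiameter = (6V/π)^⅓, Feret Length3d,
  Thickness3d, Perimeter, sphericity Shape_VA3d) with aggregate statistics.
* **A phantom generator** — branching vein trees with companions, a
  connected sinusoid mesh, pericentral steatosis droplets whose per-band
  coverage follows a programmed distance-decay profile (68/56/30/18% by
  default), and a Nissl-like intensity model (bias field, axial stripes,
  noise) — so every stage is testable with exact ground truth and no
  external data.

The compute-heavy voxel primitives (exact EDT, homotopic thinning, flood
fill, filters, resampling, tube rasterization) are implemented in C++ via
Rcpp; minimal NIfTI-1 and multi-page TIFF readers/writers are included.

## Worked example

Generate a fibrotic phantom, measure its central-vein tree, and quantify
steatosis by distance band:

```r
library(hepamorph)

cfg <- phantom_config(
  shape = c(128, 128, 128), seed = 7,
  tree_params = list(root_radius = 14, depth = 2, root_length = 90,
                     n_central = 1, n_portal = 1),
  steatosis_params = list(band_edges = c(0, 30, 60, 90, 120),
                          band_probabilities = c(0.68, 0.56, 0.30, 0.18),
                          droplet_radius = c(3, 6)))
ph <- generate_phantom(cfg)

cv <- truth_mask(ph, "central_vein")
graph <- attach_radii(build_graph(skeletonize(cv), prune_below_um = 10), cv)
summarize_morphometry(graph, cv, prod(dim(cv)) * voxel_volume(cv))
#>   mean_diameter_um n_segments total_length_um total_volume_um3 roi_volume_um3
#> 1         15.31252         18        304.0465            57737        2097152
#>   length_density_m_per_mm3 volume_fraction
#> 1                0.1449807      0.02753115

lab <- ph$truth$labels$data
other <- voxel_grid(array(lab %in% 2:4, dim(lab)), cv$spacing, kind = "labels")
band_quantify(surface_distance_field(cv), ph$truth$steatosis_mask,
              exclude_mask = other)
#>   band_lo_um band_hi_um region_volume_um3 steatotic_volume_um3  percent
#> 1          0         30            586856               384031 65.43871
#> 2         30         60            727207               398557 54.80654
#> 3         60         90            550359               167904 30.50809
#> 4         90        120            124530                20384 16.36875
```

The tree (25-µm calibre tapering over two generations) yields a mean coded
diameter of 15.3 µm and a length density of 0.145 m·mm⁻³ in the 2.1 × 10⁶ µm³
block; the measured band percentages (65.4 / 54.8 / 30.5 / 16.4) recover the
programmed 68/56/30/18 profile to within a few points — the residual is the
documented droplet-edge bleed at band boundaries.

## Analysis workflow

`analysis/` contains the numbered drivers that reproduce the study-style
analyses on phantoms, writing tables under `results/analysis/`:

| script | what it does |
|---|---|
| `01_simulate.R` | control + fibrotic arms (3 phantoms each), volumes to `scratch/` |
| `02_preprocess.R` | flat-fielding, stripe removal, normalization report |
| `03_vessels_morphometry.R` | morphometry panel + pooled-t group comparison |
| `04_steatosis.R` | classifier training curves and whole-volume mask scores |
| `05_spatial_labelstats.R` | distance-band, diameter-class and component tables |

Run any of them from the repository root, e.g.
`Rscript analysis/03_vessels_morphometry.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the held-out validation
voxel accuracy of the steatosis classifier: it builds a 128³ separable
phantom at a seed derived from `--seed`, annotates 5% of the voxels of each
class, trains to convergence, and scores the classifier on the labeled
voxels of an independent phantom generated at a different seed, writing the
result as JSON.

## Layout

```
R/            phantom, preprocess, vessels, morphometry, steatosis,
              spatial, labelstats, io, pipeline
src/          C++ voxel kernels (EDT, thinning, flood fill, filters, ...)
analysis/     numbered workflow drivers
tests/        testthat suite incl. property-based and acceptance checks
vignettes/    methods vignette (model, parameters, numerical choices)
scripts/      acceptance.R
```
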