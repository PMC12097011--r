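---
title: "Methods: 3D morphometry of hepatic vasculature and steatosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry of hepatic vasculature and steatosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model of the data

hepamorph analyzes whole-liver bright-field volumes of Nissl-stained,
resin-embedded tissue, as produced by serial-sectioning block-face
microscopes: vessel and sinusoid lumens image bright, cell-dense parenchyma
dark, and vacuolated steatotic regions at an intermediate level.  The
pipeline quantifies four things about a fibrotic liver:

1. **Vein-tree morphometry** — mean diameter, length density (m per mm³),
   number of segments, and volume fraction of the central- and portal-vein
   systems, from seeded region growing, topology-preserving skeletonization
   and a branch graph with per-point diameters.
2. **Sinusoid morphometry** — the same panel for the sinusoid network,
   extracted by thresholding with vessel subtraction and a size filter.
3. **Steatosis segmentation** — a trainable voxel classifier standing in for
   cloud deep-learning semantic segmentation, with loss/accuracy/IoU
   training curves on sparse annotations.
4. **Perivascular statistics** — steatotic volume percentage per 30-µm
   distance band from the central-vein surface, per-branch 150-µm shells
   stratified by branch diameter, and label-analysis-style per-component shape
   descriptors with aggregate statistics.

All physical quantities are computed on a 1-µm isotropic grid (anisotropic
acquisitions, e.g. 0.35 × 0.35 × 1 µm, are resampled first: trilinear for
grayscale, nearest-neighbour for labels so no label is invented).

## The phantom: a stated world with exact truth

Because the original terabyte-scale volumes are not redistributable, every
stage is validated against a synthetic phantom with exact ground truth
(`generate_phantom()`).  The generator's defaults *are* the conditions the
pipeline is designed for; they were chosen once and are not tuned per test:

* **Geometry** — 256³ voxels at 1 µm.  Central and portal vein trees enter
  from opposite faces and are confined to complementary halves of the volume
  (a lobule-like territorial split; in vivo the two systems interdigitate
  but do not touch).  Trees are recursive: child radius = parent radius ×
  0.75, two children per branch, three generations, 40-µm root radius,
  branches clamped inside the volume.  A root thinner than `min_radius` is
  emitted once, clamped up — degenerate configurations still produce
  testable output.
* **Companions** — every portal branch is flanked by an artery and a
  bile-duct tube (radius = max(2 µm, a quarter of the branch radius), offset
  ≈ branch radius + companion radius + 4 µm).  The offset direction is
  orthogonal to the lobule axis so companions never cross into central
  territory.  This encodes the anatomical cue used to tell the vein types
  apart: portal veins travel with companions, central veins travel alone.
* **Sinusoids** — random nodes at 10⁵ per mm³ joined to their three nearest
  neighbours, bridged into a single connected mesh, rasterized as 4-µm-radius
  tubes.  Sinusoids avoid a 2-µm rind around vessels *and* steatotic
  regions: pericentral steatosis destroys sinusoids in the fibrotic liver,
  and the rind keeps distinct lumen systems non-adjacent on the grid so that
  seeded growth cannot leak between them through a single diagonal step.
* **Steatosis** — spherical droplets (radius uniform in 3–6 µm, hepatocyte
  lipid scale) proposed in 30-µm distance bands around the central-vein
  surface with the programmed profile (0.68, 0.56, 0.30, 0.18).  Droplets
  may overlap and the mask is their union.  **Calibration:** accepting
  droplets with probability *p* would give a covered fraction
  1 − exp(−λ p v̄), not *p*; the per-band proposal intensity is therefore set
  by Boolean-model inversion, λ_b = −log(1 − p_b)/v̄, so the *expected
  covered volume fraction* equals the programmed probability (clamped at
  0.999 for p = 1).  Band-edge bleed by one droplet radius is the remaining
  bias; with 3–6-µm droplets in 30-µm bands it stays ~0.02–0.03, inside the
  ±0.05 recovery contract.
* **Intensity** — per-label means (parenchyma 0.35, lumens 0.75, steatosis
  0.55 on a [0, 1] scale; the published work reports no gray-level
  statistics, so these are free parameters of the stated world), a smooth
  multiplicative bias field (amplitude 0.10), additive axial sinusoidal
  stripes (period 24 voxels, amplitude 0.02 — a stand-in for sectioning and
  strip-stitching periodicity), Gaussian noise (sd 0.03), clipped to [0, 1].
* **Label precedence** — vessels > steatosis > sinusoids, making the three
  tissue classes pairwise disjoint; the droplet union before sinusoid
  carving is kept separately as `truth$steatosis_mask`, which is the mask
  all recovery tests compare against.

What a green phantom test does **not** establish: robustness to real optical
artifacts (defocus, partial volume at 0.35-µm lateral sampling, stain
gradients), to anatomically realistic lobule tiling, or to the
inflammatory-cell texture inside real steatotic regions.  The phantom's
boundaries between classes are voxel-sharp; real boundaries are not.

## Preprocessing

* **Flat-fielding** (`correct_bias`) is homomorphic: the background is
  estimated in the log domain, where a multiplicative bias is additive,
  by iteratively Gaussian-smoothing the current log-residual *clipped* to
  ±`clip_log` and accumulating it.  The clip keeps structures (lumens,
  steatosis, which sit far from their surround in log intensity) from
  leaking into the background estimate, while legitimate bias larger than
  the clip is still recovered over several passes.  Defaults
  (`iterations = 10`, `clip_log = 0.12`) meet the module's contracts
  (≥ 90% CV reduction on a bias-only field; label means restored to 2% on a
  structured field; < 1% RMS change on reapplication).  Two caveats are
  documented rather than hidden: (i) a bias with a strong *slope at the
  volume boundary* is underestimated there, because Gaussian smoothing with
  reflective boundaries assumes zero slope; (ii) at high iteration counts
  the estimator behaves like a local median and will flatten structures
  larger than `sigma_um` — the pipeline therefore uses a mild setting
  (2 passes, generous clip) before segmentation.  Gain is unidentifiable in
  flat-fielding; output preserves the global input mean.
* **Stripe removal** (`remove_stripes`) notches the stripe frequency (given
  or detected as the spectral argmax) in the Fourier transform of the
  per-slice mean profile and subtracts the reconstructed stripe from every
  slice.  This targets stripes that are constant within a slice — the
  generator's and the instrument's dominant mode — at O(volume) cost instead
  of a full per-line FFT.
* **Denoise/normalize** (`denoise_and_normalize`) is a cube median filter
  followed by an affine rescale of the `p_low`/`p_high` percentiles to
  [0, 1].  The pipeline default is `median_radius = 0`: a median filter
  brightens the narrow dark gaps separating adjacent lumen systems and lets
  seeded growth leak across them, and with Gaussian noise the segmentation
  thresholds sit ~10 σ from the parenchyma mode anyway.

## Vessel segmentation and morphometry

`region_grow()` is an exact seeded flood fill in an intensity window
(connectivity 26 by default; the window is an explicit parameter — published
workflows used interactive thresholding, so defaults here are
phantom-calibrated, not instrument-calibrated).  Seeds are *physical*
coordinates, so seed lists survive resampling.  Ties between seeds go to the
first seed in list order, documented and tested against an independent
array-shift flood oracle.

`skeletonize()` performs distance-ordered homotopic thinning: boundary
voxels are peeled inward ordered by their distance to background, removing
only *simple* points (the Malandain–Bertrand local criterion: one
26-connected foreground component among the 26 neighbours and one
6-connected background component in the 18-neighbourhood touching the
centre) while protecting curve endpoints.  Components and cycles are
preserved exactly.  Two documented behaviours: a flat-capped tube erodes
about one radius from each end before its centreline emerges, so terminal
skeleton points are extended through the mask to the boundary
(`extend_tips = TRUE`), restoring full centreline length (the package's own
cylinder contract, longest path within [95, 110] µm for a 100-µm tube,
fails without this); and a ball — a body with no tubular axis — reduces to
a short chord through its centre rather than a single voxel.

`build_graph()` clusters adjacent skeleton voxels of 26-degree ≠ 2 into
nodes, traces maximal degree-2 chains as polyline edges, designates an
anchor node on isolated cycles (which become self-edges), prunes terminal
spurs shorter than `prune_below_um`, and merges pass-through nodes until
stable.  Per-point radii are the Euclidean distance transform of the mask at
the skeleton points; the local diameter is twice that.  The morphometry
panel defines mean diameter as the *arc-length-weighted* mean of per-point
diameters (unweighted means over-count junction clusters), and length
density converts µm/µm³ to m/mm³ by the factor 10³.

Vein-type classification (`classify_vein_branches`) replaces manual
anatomical identification: a branch is portal iff more than
`companion_fraction_threshold` of its skeleton points have a companion
(artery/bile-duct) voxel within `search_radius_um`.  Arteries and bile ducts
are deliberately not distinguished from each other.

Group comparison is the pooled-variance two-tailed Student's t
(`compare_groups`), reported as mean ± s.e.m.; Welch's correction is
available behind a flag.  Zero pooled variance with differing means is
reported as t = ±Inf, p = 0 (a documented guard), identical groups as t = 0,
p = 1.

## The steatosis classifier stand-in

The cloud U-Net is replaced by a regularized logistic-regression voxel
classifier over a multi-scale feature stack: Gaussian-smoothed intensity and
local standard deviation at each scale plus the one-voxel local range
(2·|scales| + 1 features).  Scales are *FWHM* in µm (σ = scale/2.355), so
the finest admissible scale stays close to the raw voxel value — with
σ = scale, droplet-boundary blur capped held-out accuracy near 97%, below
the ≥ 99% training-curve behaviour the stand-in must reproduce.  Internally
the standardized features are augmented with their squares: steatosis
occupies an *intermediate* intensity band between dark parenchyma and
bright lumens, which no linear discriminant on intensities can select.
Unlabeled voxels never enter the loss; training is full-batch gradient
descent (deterministic given the split seed); curves are logged every 50
iterations by default, with 0.5 as the default decision threshold.
Post-processing is morphological closing (EDT-based, ball radius in µm) and
a minimum-component-volume filter.  This preserves every measured interface
of the original workflow — sparse annotation in, curves during training,
masks and volume fractions out — while training in seconds on one CPU; it
does not claim to reproduce network weights or the ~3 500-iteration curves
of the cloud service.

## Perivascular statistics

`surface_distance_field()` assigns every exterior voxel its Euclidean
distance to the nearest vessel voxel (interior voxels are NA and never enter
band accounting).  Distances are measured to the nearest foreground voxel
*centre* — a bias of at most half a voxel versus the true surface, below
every tolerance used.  Bands are half-open [lo, hi) (the published tables
write "0–30, 30–60, …" without claiming boundary ownership).  Band region
volumes partition the shell exactly — an invariant asserted in the tests.
`band_quantify()` accepts an exclusion mask: the lumens of vessels *other*
than the reference tree can hold no steatosis and would otherwise dilute the
percentages; the recovery tests exclude them.

`dilate_shell()` builds the 150-µm perivascular shell of a single branch
(interior excluded; a sub-voxel radius still yields the one-voxel rind).
`diameter_class_report()` bins branches by arc-length-weighted mean diameter
(default classes < 100, 100–150, > 150 µm), unions shells within a class
(overlap counted once), excludes all vessel interiors, and assigns
inter-class overlap to the larger-diameter class.  Classes with no branches
are absent rows, not zero rows.

## Per-component shape statistics

`measure_components()` implements the label-analysis columns as *stated
definitions under test*, not claims of bit-compatibility with proprietary
software: Volume3d is exact (voxel count × voxel volume); EqDiameter is
(6V/π)^(1/3) exactly; Length3d is the maximum Feret diameter over extreme
points in 64 Fibonacci-sampled directions plus one voxel for voxel extent
(a single voxel gets Length3d = spacing); Thickness3d is 2·max(interior
EDT) − spacing; Perimeter is the summed per-slice 2D boundary edge length
along the slicing axis (the most plausible reading of a 2D column listed
for 3D objects); the surface area behind Shape_VA3d = Area³/(36π V²) comes
from exposed-face counting with the standard 2/3 correction for the 1.5×
overestimate of face counting on randomly oriented surfaces.  Aggregate
kurtosis is the *raw* fourth standardized moment (non-excess): under a
single dominant outlier raw sample kurtosis tends to the sample size, the
pattern whole-block label tables show, which excess kurtosis cannot
reproduce.  Skewness and kurtosis of a single component are NA.

## Numerical and design choices

* Voxel membership in rasterization is centre-in-tube, with the axial
  coordinate half-open so butted segments do not double-count; a zero-length
  branch is a sphere.  Cylinder/sphere volumes are within 5% of analytic
  values at radius ≥ 5 µm on the 1-µm grid.
* The EDT is the exact Felzenszwalb–Huttenlocher transform with per-axis
  spacing weights; it is checked against a brute-force oracle.
* Connected components are labelled deterministically by scan order.
* All stochastic operations consume R's RNG, seeded once per phantom/config;
  identical configuration implies bit-identical volumes and reports.
* File formats: NIfTI-1 (spacing in the header; float64 for grayscale so
  round trips are bit-exact, int32 for labels) and baseline uncompressed
  16-bit multi-page TIFF (no spacing — the reader requires it as an
  argument).  Both readers/writers are implemented in the package because
  the target environment ships no R imaging I/O; they are cross-checked
  against independent Python readers in the test suite.

## Known limitations

* The phantom does not model lobule tiling, hemodynamics, inflammatory
  cells, partial-volume rendering or scanner PSF; thresholds calibrated on
  it will need re-calibration on real data.
* Flat-fielding underestimates bias with strong slope at the volume
  boundary and, at aggressive settings, flattens structures at the
  estimation scale (see above).
* The stripe filter assumes in-plane-constant stripes; oblique or in-plane
  periodic artifacts pass through.
* Skeleton-based segment counts depend on junction-cluster merging and spur
  pruning; compare counts only at a fixed `prune_below_um`.
* The vein-type classifier assumes companions are resolvable and adjacent
  to portal branches; it will call an unaccompanied portal stump "central".
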