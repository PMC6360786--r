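---
title: "Methods: voxel-based maize phenotyping from terrestrial laser scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-based maize phenotyping from terrestrial laser scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`maizetls` reimplements a terrestrial-laser-scanning (TLS) phenotyping
workflow for gridded maize drought trials: a plot is scanned at six growth
stages (D20–D95, from six-leaf to physiological maturity), preprocessed
into a height-normalized cloud, split into individual plants on the 50 cm
x 30 cm planting grid, and summarized per plant as height, plant area
density per vertical stratum (PAD), plant area index (PAI) and projected
leaf area fraction (PLA). Grain yields of the same varieties under control
and drought irrigation feed three tolerance indices (YRR, DSI, DRI) whose
distance-based clustering splits the varieties into three tolerance groups,
for which growth dynamics and vertical PAD profiles are compared.

Because no field data are deposited with the source study, the package
ships a synthetic maize-scene generator with exact ground truth; every
downstream stage is validated against that truth.

## Preprocessing model

**Outlier removal** is the classic statistical filter: the mean distance of
each point to its k nearest neighbors (default k = 10) is compared with the
global mean plus n standard deviations (default n = 3) of those means. The
source workflow names the rule but not k or n; the defaults are standard
practice.

**Ground classification** is a simplified progressive TIN densification.
Seeds are per-cell minima on a 1 m grid, screened against the median
elevation of their neighboring seeds (a cell containing only overhanging
canopy would otherwise contribute a canopy seed); boundary pseudo-vertices
at the extent corners keep the whole plot inside the triangulation. Points
within 0.05 m vertical distance of their containing facet and within 30
degrees of its vertices are accepted as ground over three densification
iterations. The published algorithm's bending-energy refinements are out of
scope; on the synthetic scenes the simplified filter labels ground with
roughly 95% accuracy, and the pipeline additionally discards normalized
points below 0.02 m so that residual mislabeled ground returns (which
concentrate at plot corners, where the seed TIN is weakest) cannot leak
into the canopy rasters.

**DTM interpolation** is ordinary kriging at 5 cm resolution with an
exponential variogram fitted by weighted least squares (15 lag bins,
weights N(h)/h^2) and a zero nugget, so the surface honors the data
exactly; each cell is predicted from its 24 nearest ground points, and a
singular system falls back to inverse-distance weighting with a warning.
The variogram family and fitting scheme are package choices — the source
names only "ordinary kriging".

**Height normalization** subtracts the bilinearly interpolated DTM.
**Density resampling** randomly thins the cloud (seeded) until the mean 3D
nearest-neighbor distance is within 5% of the target. Note one subtlety:
on a perfectly regular grid, random thinning first *collapses* the
nearest-neighbor constant toward its Poisson value, so the retained
fraction needed to double the mean distance is far below the naive 1/4;
the 1/4 density-scaling intuition holds for spatially random (already
thinned) clouds, which is the regime the operation is meant for.

## Phenotype extraction

**Height** is the maximum normalized z of the plant's cell — deliberately
sensitive to residual outliers, which is why denoising precedes it.

**Voxel profiling.** The cell is voxelized (binary occupancy, grid anchored
at the cell corner) and the five strata are plant-relative fifths of the
plant's height, root layer excluded. Two PAD estimators are exposed:

* `compute_pad()` evaluates the printed formula
  `PAD_k = cos(theta_c)/G x 1/dH x n_l(k)/(n_l(k)+n_p(k))` with `n_l`,
  `n_p` the occupied/empty voxel counts of the whole layer. Taken
  literally, this ratio is a volume-fill fraction: at millimetre voxel
  sizes it is O(10^-3) and cannot reach the magnitudes the source tables
  report, so it is kept as the faithful arithmetic form.
* `compute_pad_profile()` sums the occupied fraction of every
  one-voxel-thick horizontal slab within the stratum — the voxel-based
  canopy-profiling (contact-frequency) estimator that the printed formula
  abbreviates. Its magnitudes match destructive leaf-area truth and its
  voxel-size response reproduces the reported rise-then-plateau behavior.
  The pipeline, calibration and recovery all use this form.

**PAI** is reported in two unit conventions: the printed plain sum of the
five PADs (m^2/m^3 summed — unit-inconsistent but faithful), and the
height-weighted sum `sum(PAD_k x dH)` (m^2/m^2), which is the quantity
comparable to ground truth; the phenotype table carries both (`pai_printed`
and `pai`).

**Voxel-size calibration** sweeps 1–12 mm in 0.5 mm steps and selects the
size minimizing the summed per-layer |PAD - truth|. Below the sampling
pitch voxels miss the surface (underestimation); past it the estimate
plateaus and slowly inflates as voxelization over-counts tilted surfaces.
The selected size is also reported as a multiple of the plant's average
point distance (mean 3D nearest-neighbor distance). On synthetic plants
this multiple lands near 0.9–1.0, slightly below the published 1.5x
anchor: the 3D nearest-neighbor mean is inflated by range noise relative
to the 2D effective sampling pitch, and the contact-frequency estimator's
saturation value exceeds truth (voxelized area over-counts inclined
surfaces by the l1-norm of the surface normal, and cos(theta_c)/G doubles
it), so the error minimum sits just below full surface coverage.

**PLA** projects the cell's points to the X–Y plane and rasterizes. The
printed pixel rule — the minimum pairwise X–Y distance — degenerates on
real clouds: any two leaves crossing in projection give a near-zero
distance, the raster then merely counts points and measures area, not
projection. `compute_pla()` keeps the literal rule with a pixel floor; the
pipeline sets the floor to 1.75x the median 3D nearest-neighbor distance,
i.e. the effective sampling pitch, which fills the raster under canopy
while keeping aliasing error small. The raster tiles the full 0.50 x
0.30 m cell, so PLA is a fraction of the ground cell.

## Drought analysis

YRR, DSI and DRI are computed from per-variety mean yields and the
population means; all three are invariant to rescaling every yield by a
common factor. Classification z-scores the index triple (DRI's larger
scale would otherwise dominate) and applies Ward-linkage agglomerative
clustering on Euclidean distances, cut at k = 3; groups are labeled
L1/L2/L3 by descending mean YRR (L1 = largest loss = least tolerant). The
source names only "distance-based clustering (SPSS)"; Ward is the
deterministic standard for small k. Varieties with non-finite indices are
excluded with a warning, mirroring the trial's exclusion of varieties with
incomplete drought samples. Stage comparisons use Welch's unpaired t-test
pooling individual plants per group, flagged at 0.05 and 0.01 with no
multiple-testing correction — matching the source's reporting levels and
its silence on the test and correction.

## The synthetic world

The generator builds each plant from a vertical stem cylinder and leaves
modeled as ruled ribbon surfaces: a drooping arc centerline (inclination
falling from beta0 to beta0 - 45 degrees at the tip) with an elliptically
tapered width. Because the ribbon's lateral direction is horizontal and
perpendicular to its vertical plane, its area is exactly length x width x
taper, so the width is solved in closed form and the per-stratum one-sided
areas equal the request to machine precision. Truth is nevertheless
computed from the triangle mesh itself — per-layer areas by exact slab
clipping, PAD as area/(cell footprint x dH), PAI as the height-weighted
sum, and PLA by 1 mm rasterization of the projected union — so leaves
crossing layer boundaries are handled honestly.

Stated-world choices, fixed once:

* Leaf inclination: mean 50 degrees above horizontal, 15 degrees spread
  (maize canopies lean erectophile); leaves emerge distichously in two
  opposite ranks oriented perpendicular to the planting row, which stacks
  projections and keeps the projected fraction low at high PAI, as in real
  maize stands.
* Leaf size grows with stature (about 0.01 m^2 one-sided for juveniles to
  0.035 m^2 at full height) and leaf length peaks mid-canopy with short
  flag leaves near the tassel (lateral reach caps of 0.34/0.45/0.45/0.36/
  0.225 m by stratum).
* Point sampling is a jittered lattice in each surface's own plane at the
  sensor pitch (default 4 mm), emulating the evenly spread pattern of a
  density-resampled cloud, with 1 mm isotropic Gaussian noise (phase-shift
  TLS ranging error at close range; the often-quoted 2 mm figure is a
  multi-scan registration systematic, not per-point noise).
* Terrain is a sum of low-frequency sinusoids scaled to the requested
  amplitude (default 2 cm over the plot); ground points lie exactly on it.
* Occlusion removes a fraction of plant points (default 10%) with a bias
  toward the lower canopy, mimicking how stems and sheaths scan poorly;
  outliers (default 0.5%) are uniform in the bounding box.
* Yields: per-variety lognormal-ish baselines around 200 g/plant; drought
  yields are the control scaled by (1 - group reduction) with
  multiplicative replicate noise of coefficient cv, truncated at zero, so
  cv = 0 reproduces the configured group reductions exactly. The default
  calibration anchors are the reported 85%/48%/27% group-mean reductions.
* A cell's true PLA is the projected union of *all* plants' surfaces over
  that cell footprint — neighbor overhang included — which is what a nadir
  image of the cell records and what the cell's points contain. The
  standalone single-plant truth uses the plant's own mesh only.

What the generator does not emulate: ray-traced visibility (occlusion is
statistical), multi-return waveforms, scan-line anisotropy, registration
offsets between scans, wind deformation, weeds, and senescent leaf shape
change. A green recovery test therefore establishes that the algorithms
recover their own stated world, not that the field accuracies of the
source study are reproducible.

## Recovery experiments and their honest limits

`recovery_experiment()` first calibrates the voxel multiplier on three
reference plants (the field procedure: sweep, compare with truth, apply
the found multiple everywhere — in this world it lands near 0.94, not
1.5), then builds one scene per growth stage, with per-variety
plant specs drawn from the published per-stage height and PAI ranges —
each scan date of a trial covers one stage, so plants within a scene have
comparable stature. Estimates pooled over all stages are compared with
truth by squared Pearson correlation (the printed R^2 statistic penalizes
scale bias so harshly that a correct-but-biased estimator scores near
zero; "regression of estimated on true" is the meaningful recovery
measure).

Two documented effects bound what the pipeline can achieve in this world:

* Leaf overhang across cells. Mid-canopy leaves reach ~0.45 m laterally
  while columns are 0.50 m apart, so a tall variety's leaves intrude into
  a shorter neighbor's cell above that neighbor's apex. Grid segmentation
  deliberately does not reassign them (faithful to the field method, which
  lists this as a known error source), so a few plants per scene carry
  height errors of +0.05–0.4 m. Pooled height R^2 stays near 0.98–0.99,
  but the fraction of plants within 2 cm of truth saturates around
  0.8–0.9 — consistent with the source's own 0.15 m height RMSE, and
  irreconcilable with a 95%-within-2-cm expectation in any world that
  keeps faithful overhang.
* Exact truth. The synthetic PLA truth is errorless, so PLA recovery
  (R^2 ~ 0.99) can exceed height recovery — unlike the source's
  validation, where the PLA reference came from a second imperfect sensor
  (UAV imagery). The published accuracy ordering (height > PLA) reflects
  that reference noise, not the pipeline.

## Numerical details worth knowing

* Grids and rasters use half-open cells `[lo, hi)`; a point exactly on a
  shared edge belongs to the higher-index cell, never to both.
* Delaunay triangulation of near-regular seed grids is degenerate
  (cocircular quadruples); seeds get a deterministic sub-micron jitter
  before triangulation, used only for the connectivity.
* Kriging windows collapse duplicate data locations by averaging, return
  the data value outright at a colocated target, and fall back to inverse
  distance on singular systems.
* `classify_tolerance` sorts varieties by id before clustering so the
  partition is invariant to input order; an all-identical input is flagged
  degenerate but still returns a deterministic split.
* Change rates are undefined (NA, never 0) at the first stage and after a
  gap; two zero-variance equal samples give p = 1 by convention.
* Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state, so scenes are byte-reproducible.
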