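---
title: "Counting neurons in light-sheet volumes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting neurons in light-sheet volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsmcount)
```

## The problem

Light-sheet microscopy (LSM) of cleared, immunolabeled mouse brains produces
intact 3D volumes in which a nuclear neuronal marker (NeuN) labels every
neuron. Given such a volume and an aligned integer region label map (an
atlas), we want, per region: the neuron density (neurons/mm^3), an estimate of
the total neuron number, and the variability of both across counting sites
and across specimens. Counting every voxel of a whole brain is wasteful;
instead the package implements a *digital optical fractionator*: cubic
counting windows are placed uniformly at random strictly inside the region,
neurons are segmented and counted inside each window, and the region density
is the mean of the window densities. Because every position inside the region
is sampled with equal probability, the estimator is design-unbiased with
respect to window placement; its spread over windows measures the spatial
heterogeneity of the region.

`lsmcount` implements the full chain — sampling, segmentation, instance
separation, volume-filter counting, summary statistics, and evaluation —
together with a synthetic phantom generator so that every stage is testable
without microscope data.

## Conventions

* **Axis order** is `(z, y, x)` everywhere, 0-based voxel indices, with the
  center of voxel `(z, y, x)` at physical position `(z*dz, y*dy, x*dx)` um.
* **Spacing is mandatory.** There is no "assume 1 um isotropic" fallback:
  the watershed topography, the erosion schedule, the volume filter, and the
  density denominator all work in physical units, and a silently wrong
  spacing would corrupt all of them. Readers error when a file carries no
  calibration and no override is given.
* Densities are reported per mm^3; object volumes in um^3 (1 mm^3 = 1e9 um^3).

## Sampling: the counting windows

`sample_subvolumes()` draws cube origins uniformly over every grid position
where the cube fits, and accepts a placement only if the fraction of cube
voxels carrying the target region label reaches `inclusion_threshold`
(default 1.0). Strict screening is the only rule that guarantees every
counted object is attributed to a single region; the threshold is
configurable for regions too thin to contain full cubes. Key choices:

* **Cube edge 100 um** (default), voxelized per axis as
  `round(edge/spacing)` — at the reference spacing of (4, 1.8, 1.8) um a
  cube spans 25 x 56 x 56 voxels. The *realized* physical volume
  (100 x 100.8 x 100.8 um^3 there) is the density denominator, not the
  nominal (100 um)^3; rounding to voxels would otherwise bias every density
  by the same few permille.
* **15 windows per region** (default): enough for a stable mean and an
  informative SD while keeping region runtime low, and a constant sampling
  depth across regions keeps cross-region comparisons balanced.
* **Overlap is permitted.** Placements are independent; forbidding overlap
  would couple the draws and bias the estimator in small regions. The plan
  records seed, rejection count and origins, so a non-overlapping variant
  could be added without changing the contract.
* **Retry cap `10000 * n`**: sampling a region that cannot host the cube
  fails loudly with the observed acceptance rate instead of spinning.

## Segmentation: sparse-label random forest

A random forest classifies every voxel as neuron vs background, in the
lightly-supervised regime where the user scribbles inside roughly **20
nuclei** plus a comparable amount of background. Features per voxel are the
standard multi-scale family: Gaussian-smoothed intensity, gradient magnitude,
Laplacian of Gaussian, difference of Gaussians (sigma, 2 sigma), and the
three sorted Hessian eigenvalues, at scales {1.6, 3.2, 6.4} um, plus the raw
intensity — 22 features at the defaults. Scales are physical and converted
per axis to voxel sigmas, so anisotropic voxels are handled correctly; a
scale below half the coarsest voxel dimension triggers a warning because the
feature is degenerate along that axis (this includes the 1.6 um default at
4 um z spacing — the scale still contributes laterally).

Forest hyperparameters: 100 trees, unlimited depth, Gini splits,
`floor(sqrt(p))` features per split, bootstrap resampling, fixed seed. Small
training sets need the variance reduction of many trees; all values are
recorded in the model. The model stores a *fingerprint* (feature names,
scales, spacing) and refuses feature stacks computed with any other
configuration — in particular, a model trained at one voxel size will not
silently run on a volume with another. Models serialize to a single JSON
file with an md5 checksum over the fingerprint; a tampered file refuses to
load. Binarization uses probability >= 0.5 by default (configurable); the
threshold is a free parameter of any probabilistic segmenter and 0.5 is the
symmetric choice.

## Instance separation: erosion-seeded watershed

Touching nuclei form one connected component after thresholding. To split
them:

1. the anisotropy-aware Euclidean distance transform of the mask is computed
   (exact, per-axis physical spacing);
2. the mask is eroded in steps of the finest voxel dimension (implemented as
   thresholding the distance transform); when the next erosion would delete a
   connected component entirely, its current remnant becomes a seed. This
   schedule is parameter-free and scale-adaptive: an isolated nucleus yields
   exactly one seed, a dumbbell of two nuclei splits into two cores before
   vanishing and yields two;
3. basins are flooded from the seeds over the negated distance transform;
   voxels where two basins meet become *dams* and are assigned to
   background. Instance volumes are therefore conservative by at most a
   one-voxel shell per split.

Connectivity defaults to 26 for seeds, flooding and components alike (the
common 3D binary default; 6 is available). Because dams separate basins,
relabeling the dam-free binary with `connected_components()` reproduces the
basins exactly; the pipeline performs that relabeling step explicitly.

## Counting: the volume filter

Each instance of volume `V` contributes to the count:

* `0` if `V < v_min` (debris, shot noise, clipped slivers),
* `1` if `v_min <= V <= v_max`,
* `max(2, round(V / v_ref))` if `V > v_max` — an object too large to be one
  neuron is treated as a fused cluster and partitioned by the mean
  single-neuron volume `v_ref`. Nearest-integer partitioning is the
  minimal-assumption rule and is unit-consistent; halves round up
  (`floor(x + 0.5)`), avoiding the platform-dependent banker's rounding.

Defaults are derived per dataset from the empirical instance-volume
distribution: `v_ref` = median of the 20th-80th percentile volumes,
`v_min = 0.25 v_ref`, `v_max = 2 v_ref`. All three are settable everywhere.

**Edge rule.** An object clipped by a window boundary poses the classic
stereological edge problem: counting every fragment above `v_min` inside the
window is upward-biased (for 4.5 um nuclei in a 100 um cube the analytic cap-
volume argument gives roughly +9%), which would visibly break the estimator's
consistency. The pipeline therefore segments a *padded* crop (default halo
10 um, about two nucleus radii) and counts an instance iff its **centroid**
falls inside the half-open core window — the associated-point rule. Each
object has exactly one centroid, so it is counted in exactly one window
tiling position and the estimator stays unbiased.

Summaries use the sample SD (n-1); the total-number estimate is mean density
x label-map region volume, rounded to the nearest integer. Cross-specimen
variability uses the coefficient of variation (sample SD / mean). The
raw-vs-corrected comparison metric is
`|raw - corrected| / corrected * 100` per cent.

## Evaluation

`match_instances()` scores predictions against ground truth by greedy
one-to-one matching: centroid criterion (physical distance <= tol, closest
pairs first; default tol = the mean true nucleus radius) or
intersection-over-union (default 0.3). Greedy distance-ordered matching is
deterministic and standard in cell-detection scoring; the test suite
documents its agreement with brute-force optimal assignment on unambiguous
scenes. `f1_score()` returns precision, recall and F1, with the degenerate
all-empty case defined as (0, 0, 0) plus a warning.

## The synthetic phantom

`generate_phantom()` emulates a NeuN LSM channel: ellipsoidal nuclei (base
radius ~ N(4.5, 0.5) um, +/-15% per-axis jitter) rendered in physical units
on an anisotropic grid (default (4, 1.8, 1.8) um — the voxelization at which
a 100 um cube is 25 x 56 x 56 voxels), per-nucleus intensities
N(180, 20) on a textured background (mean 30 plus smoothed noise of SD 10 —
deliberately non-flat so a global threshold cannot solve the task), Gaussian
PSF stand-in of 1.5 um, additive read noise SD 8, optional Poisson
resampling. The nucleus count is Poisson(density x volume); a stated
`touching_fraction` of nuclei is placed as explicit near-contact pairs at
0.9 x the sum of their radii (known merge topology for watershed tests), and
the remaining placements reject accidental contacts. Ground truth carries
the instance grid, exact centroids, radii and rendered volumes.
`generate_region_phantom()` wraps the same machinery in rectangular labeled
regions with a zero margin and per-region density factors.
`apply_deformation()` resamples volumes (trilinear) or label/instance grids
(nearest-neighbour, so no IDs are invented) through a dense displacement
field in um; `scaling_field()` builds the uniform-shrink field used to
emulate uncorrected tissue morphology, where a shrink `s` per axis inflates
naive densities by `1/s^3`.

The paper-facing intensity statistics of real SmartSPIM data are not
published, so the phantom's contrast and noise levels are plausibility
choices, fixed once and all configurable. What a green test establishes: the
estimator chain is correct and unbiased on data matching its assumptions
(ellipsoidal nuclei, stationary background, known spacing). What it does not
establish: performance on real tissue with vasculature shadows, striping,
antibody gradients, or densely packed granule layers — the workflow's known
failure mode, where counting hinges entirely on the volume filter.

## Numerical and degenerate-input choices

* Separable Gaussian convolution with symmetric (reflect) boundary; kernel
  radius 3 sigma. Derivatives by central differences on the smoothed volume
  (replicate boundary).
* The distance transform is the exact squared-parabola algorithm with
  per-axis sample spacing; flooding order ties are broken by insertion order,
  making the watershed fully deterministic.
* Empty mask -> zero instances; empty region -> explicit error; single-class
  annotations -> error (training needs both classes); zero corrected density
  -> error rather than NaN.
* All randomness flows through explicit integer seeds; library calls save
  and restore the caller's RNG state.
* TIFF float data is written as 64-bit by default so write/read round trips
  are bit-identical; NIfTI files are written with z as the first stored
  dimension (the package's memory order) and orientation metadata is not
  interpreted.

## Limitations

* The random forest is trained per spacing/feature configuration; reuse
  across specimens is supported (same spacing) but portability across stains
  or resolutions is intentionally refused by the fingerprint.
* The sampler implements independent uniform placement only — no
  systematic-uniform grids, no disector frames with forbidden planes.
* Whole-brain out-of-core volumes are out of scope; the package operates on
  in-memory arrays (a 300 GB brain is processed region by region upstream).
* Densities in regions whose nuclei the optics cannot resolve individually
  degrade to volume-filter extrapolation, inheriting its `v_ref` assumption.
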