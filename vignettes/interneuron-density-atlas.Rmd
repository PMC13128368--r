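---
title: "Voxel-wise interneuron density atlases: models and methods"
author: "striatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise interneuron density atlases: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatlas)
```

## The problem

The caudoputamen (the rodent dorsal striatum) hosts sparse GABAergic
interneuron populations — somatostatin- (SST), parvalbumin- (PV) and tyrosine
hydroxylase-expressing (TH) classes — whose spatial arrangement constrains
what each striatal territory can compute. Given per-cell soma coordinates in
a common coordinate framework (one CSV row per detected cell, with
anteroposterior/mediolateral/dorsoventral positions plus subtype, animal,
hemisphere and sex labels), `striatlas` builds a voxel-wise 3D density atlas
and quantifies its large-scale organisation in three complementary ways:

1. **Voxel maps** — hemisphere-bootstrap mean and SE of density
   (cells/mm^3) on a 150 µm cubic lattice, smoothed, binned into pooled
   density quantiles, and summarised as a subtype predominance map.
2. **Axis gradients** — densities collapsed into 150 µm slabs along each
   anatomical axis and fitted with a random-intercept linear mixed model,
   `Density ~ Coordinate + (1 | Hemisphere)`, optionally with sex and a
   sex-by-coordinate interaction.
3. **Subregion composition** — per-hemisphere densities in four
   cortical-input-defined territories (DMCP, LCP, TCP, aVMCP), compared with
   random-intercept models and Sidak-corrected pairwise Wald contrasts.

A synthetic module generates a toy reference space and inhomogeneous-Poisson
cell patterns with known structure, so every stage is testable with no
external data.

## The analysis grid

The region label volume (NRRD or NIfTI) is covered by cubic voxels of edge
`edge_um` (default 150 µm), anchored at the region bounding-box corner
snapped to the label raster; a voxel is a candidate iff at least one
region-labelled raster voxel centre falls inside it. Candidates are then
eroded by a Chebyshev (L∞) distance rule: a voxel is dropped when its centre
lies within `d_boundary_um` (default 50 µm) of a region-exterior raster
voxel centre, or within `d_ventricle_um` (default 175 µm) of a
ventricle-labelled raster voxel centre. The ventricle margin exists because
periventricular ependymal cells express PV and would otherwise contaminate
PV density estimates near the ventricular wall.

Two conventions are deliberate and documented rather than prescribed by the
source material:

* **Distances are voxel-centre-to-voxel-centre at the label raster's native
  resolution**, with a strict `< d` exclusion. This is reproducible at any
  raster spacing, but it does make the effective erosion depend on how grid
  centres land relative to raster centres: on a 50 µm raster aligned with
  the 150 µm grid, centre distances are multiples of 50 µm, so the 50 µm
  boundary rule removes exactly the voxels whose centre raster voxel is
  exterior; on a 75 µm raster, grid centres fall midway between raster
  centres and the same rule erodes slightly deeper. Both thresholds are
  configuration, not constants.
* **Positions beyond the raster extent count as exterior** for the boundary
  rule, so a region touching the raster edge is eroded there too.

## Density estimation

The independent sampling unit is the **hemisphere** (all cells of one
subtype in one hemisphere of one animal). Left-hemisphere cells are first
reflected across the midline (`ml ← 2·midline − ml`; cells exactly on the
midline count as right-hemisphere — a measure-zero set needing a
deterministic rule), so hemispheres pool into one reference side while the
side label is retained for lateralisation questions.

Each bootstrap replicate draws *n* hemispheres with replacement from the *n*
available and computes per-voxel density as summed counts over the drawn
hemispheres divided by (*n* × voxel volume) — a per-hemisphere density, so
maps are comparable across subtypes with unequal *n*. The map's mean and SE
are the mean and SD over `n_boot` (default 1000) replicates. Resampling
cells within hemispheres instead is available (`bootstrap_unit = "cell"`)
for sensitivity analysis, but hemispheres are the defensible unit: they are
what the mixed models treat as exchangeable.

Cell-to-voxel assignment uses half-open intervals `[lo, hi)` (a cell exactly
on a shared face belongs to the higher-index voxel), so counts are conserved
exactly; the tests assert cells-in = cells-binned + cells-excluded at every
stage.

Smoothing uses a truncated Gaussian kernel (σ = 0.5 voxel = 75 µm on the
default grid, radius 3σ) with **mask renormalisation**: each output voxel is
the kernel-weighted mean over included voxels only, weights renormalised to
sum to one inside the mask. This preserves constants exactly, never bleeds
density into or out of the excluded margin, and reduces to ordinary discrete
Gaussian convolution when the mask is full. Smoothing is applied to the
bootstrap mean after aggregation; the SE map is left untouched.

Pooled quantile binning computes the k/15 (k = 1..15) type-7 empirical
quantiles of the pooled included-voxel densities of all subtype maps, and
assigns each voxel the index of the first threshold at or above its density.
Tied thresholds collapse to the highest index, so a degenerate all-equal
pool lands entirely in the top bin; with distinct values the bins partition
the pool into equal slices. The predominance map takes the per-voxel argmax
of the smoothed means, breaking exact ties by the fixed subtype order
(SST, PV, TH) and counting them.

## Axis gradients

An axis profile slices the included grid into 150 µm slabs along AP, ML or
DV; per hemisphere and slab, density = cells in included voxels of the slab
divided by the slab's included volume. Slabs with no included voxel are
dropped for all hemispheres. The gradient model is fitted on these
**plane-level** observations (hemispheres × retained planes observations;
e.g. 12 × 27 = 324 for a full AP profile) rather than on per-voxel
densities: plane-level observations are what the profile figures display,
and the per-voxel alternative mostly multiplies the observation count
without adding independent information about an axis-level slope. The unit
is switchable (`lme_unit: plane|voxel`) for sensitivity analysis.

The engine (`fit_random_intercept`) fits the one-way random-intercept model
by maximum likelihood through `lme4`, with Wald z (normal) inference on
fixed effects — at these observation counts (≥ ~240) the difference from
t-based small-sample corrections is negligible, and Wald contrasts extend
naturally to the pairwise comparisons below. REML is available. The
coordinate enters uncentred, in mm, so the slope is in cells/mm³ per mm and
the intercept is the extrapolated density at coordinate zero. Sex is
treatment-coded with female reference, so the coordinate coefficient is the
female simple slope and the interaction coefficient is the male-minus-female
slope offset. The slope is a summary of global directional bias; several
real profiles are visibly non-monotonic, and the model makes no claim about
that structure.

If the mixed fit fails outright, the engine falls back to its ordinary
least-squares limit (random-intercept variance zero) with a warning; a
boundary ("singular") fit is kept, since its fixed effects coincide with the
OLS solution anyway.

## Subregion composition

Cells are assigned to parcels by per-cell label lookup; cells on unlabelled
region voxels are "unassigned", counted and excluded from densities. Parcel
volumes are computed after intersecting the parcellation with the region
mask. Composition is tested in both pivots of the same hemisphere × parcel ×
subtype density table: subtype differences within each subregion, and
subregion differences within each subtype, each as
`Density ~ Factor + (1 | Hemisphere)` with a joint Wald chi-square omnibus
and all pairwise Wald contrasts, Sidak-adjusted
(`p_adj = 1 − (1 − p)^m`, m = 3 subtype pairs or 6 subregion pairs).

One caveat is inherited from the design: in the within-subregion pivot each
hemisphere carries a single subtype, so within a stratum every hemisphere
contributes exactly one observation and the random intercept is confounded
with the residual (and with the tested factor). The model is specified with
the intercept anyway; where the mixed fit is consequently not estimable the
engine reports its ordinary-least-squares limit (identical fixed effects,
random-intercept variance zero) with a warning, and `fixed_only = TRUE`
requests that limit explicitly. The tests exercise both paths.

## The synthetic generator

`synthetic_config()` describes a one-hemisphere ellipsoidal region
(semi-axes 2.0/1.6/1.7 mm — extents that yield 27/22/23 retained 150 µm
planes along AP/ML/DV, the plane counts of a full-size caudoputamen
profile) on a 50 µm raster, with a thin ventricle sheet on part of the
medial face and four octant-like parcels (posterior cap = TCP; the rest
split dorsomedial/lateral/ventromedial). Cells are drawn per hemisphere from
an inhomogeneous Poisson process whose intensity is

    λ(x) = max(0, baseline + sex offset + u_hemisphere + Σ_axis slope·x_axis
               + ε_section)

with `u ~ N(0, hemisphere_sd)` and `ε ~ N(0, section_noise_sd)` drawn per
hemisphere × 150 µm coronal section. The linear (truncated) intensity makes
the fitted linear mixed model correctly specified wherever λ stays positive,
giving a clean recovery surface; the truncation itself reproduces a salient
feature of the real maps (TH density falling to near zero in the tail).

The section-noise term deserves its own paragraph. Pure Poisson sampling
would leave plane-level residual SDs of a few tens of cells/mm³, an order of
magnitude below what real profiles show, and — because Poisson density
variance scales inversely with slab volume — would concentrate variance in
the thin edge slabs exactly where the slope's leverage is largest,
distorting Wald calibration for a reason real data do not share. Real
residual variation is dominated by per-section detection and registration
variability, which is common to all cells of a section. The generator
therefore adds an iid Gaussian intensity offset per hemisphere × coronal
section (default SD 400 cells/mm³, the plane-level residual scale of real
fits), at the analysis-plane pitch so the value is read directly as the
model's residual SD.

Generator defaults are the study conditions: 12 hemispheres per subtype
(3 animals/sex × 2 hemispheres), hemisphere SD 300, axis slopes at the
magnitudes reported for real SST/PV/TH gradients (stored as female slope
plus male offset where sex interactions are modelled: TH AP 212.9 + 57.85,
TH DV 441.6 + 169.2, PV ML −61.34 + 124.3, in cells/mm³ per mm), and
baselines of 1000–1300 cells/mm³ chosen once to sit in the realistic
striatal interneuron density range. Left hemispheres are generated mirrored
so the mirroring stage is always exercised. The seed fully determines every
output.

What the generator does **not** emulate: detection errors and non-somatic
label contamination, registration distortion, non-monotonic density
structure (bowl-shaped ML profiles), inter-animal (as opposed to
inter-hemisphere) correlation, and anatomically realistic parcel geometry.
Passing recovery tests therefore show that the pipeline estimates what it
claims to estimate under its own assumptions — not that those assumptions
exhaust real tissue.

## Calibration experiments and problem sizes

`recovery_experiment()` runs the full pipeline (simulate → mirror → filter →
grid → erode → collapse → mixed model) per replicate and reports bias, RMSE,
95% CI coverage and the rejection rate at α = 0.05. The packaged
calibration runs use 100 replicates at the study scale above, with a 75 µm
generation raster (generation voxels nest exactly 2:1 inside the 150 µm
analysis planes, keeping section noise aligned with analysis slabs) and the
AP axis — the axis whose slabs are the coronal sections the noise model
lives on. Expectations asserted by the test suite: mean slope bias below 5%,
coverage within [0.90, 0.99], and type-I error within 0.05 ± 0.03 under a
slope-zero generator; a generated male–female slope offset of 60 must be
recovered within 2 SEs in at least 90 of 100 replicates.

Numerical details fixed by design: type-7 (linear interpolation) quantiles;
Gaussian kernel truncated at 3σ; σ = 0 smoothing is the identity; zero
exclusion distances exclude nothing (strict inequality); `sample.int`-based
bootstrap draws so identical seeds give bit-identical maps; NRRD output in
little-endian raw encoding with NA encoded as −1 (density/SE) or 0 (bin and
predominance codes, which are 1-based).

## Known limitations

* The Chebyshev erosion depth depends mildly on raster/grid centre
  alignment (see above); comparisons across rasters of different spacing
  should hold the spacing fixed.
* Wald z inference is mildly anticonservative for very small hemisphere
  counts; with fewer than ~6 hemispheres, treat p-values as descriptive.
* The within-subregion composition model retains a random intercept that is
  confounded with subtype; its omnibus p-values lean on the fixed-effects
  part of the fit.
* Plane-level observations inherit spatial autocorrelation along the axis;
  the model treats planes as exchangeable given the hemisphere intercept,
  as the published analysis does.
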