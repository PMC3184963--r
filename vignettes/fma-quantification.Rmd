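---
title: "Quantifying the renal microvasculature from fluorescent microangiography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the renal microvasculature from fluorescent microangiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmaquant)
```

## The measurement problem

Fluorescent microangiography (FMA) delineates the renal microvasculature by
what it *is* rather than by what it expresses: the vascular tree is perfused
with a low-melting-point agarose carrying sub-resolution fluorescent
microspheres, so that every perfused lumen fills with fluorescent gel.
Confocal optical sectioning of thick kidney slices then yields a z-stack in
which the green channel traces vessel lumina and the red channel carries
tubular autofluorescence. Compared with endothelial immunostaining, this
sidesteps antigen redistribution in disease and cross-reactivity with
lymphatic endothelium.

The quantities of interest, per animal, are:

* **glomerular capillary volume** — total lumen volume inside a glomerular
  tuft (µm³);
* **glomerular volume** — the volume of the tuft envelope, modelled as an
  ellipsoid, V = 4πabc/3;
* **glomerular capillary density** — the quotient of the two (dimensionless);
* **peritubular capillary density** — lumen volume fraction of a cortical
  field after the glomerular tufts have been excluded.

`fmaquant` implements this pipeline — segmentation, voxel-counting
volumetry, ellipsoid fitting, density computation — together with the
conventional 2D immunostain comparator (proportional stained area), the
semi-quantitative glomerulosclerosis index, and the group statistics used
for such studies. Because no reference images ship with the method, a
synthetic phantom generator with exact ground truth is a first-class part of
the package: every stage of the pipeline is validated by parameter recovery
on phantoms.

## Voxel-counting volumetry

Capillary volume is computed exactly as a per-slice analysis would: the
positive pixel area of each optical section times the section spacing,
summed over the stack. With a lateral pitch `dx = dy` and axial step `dz`
this telescopes to

> total positive voxel count × (dx · dy · dz),

computed with exact integer counting. The axial step defaults to
0.8141 µm throughout the package. The lateral pitch of the acquisition
configuration is not derivable from objective magnification alone, so the
package never assumes it silently: readers require a JSON geometry sidecar
or an explicit override, and generators record 0.73 µm/pixel (typical for a
20× objective at zoom 2) in their metadata.

## The glomerular envelope

The tuft envelope is estimated from the segmented lumen mask (restricted to
the glomerular ROI and morphologically closed with a metric ball of 2 µm,
logged in provenance) by **moment matching**: the centroid gives the centre,
the eigenvectors of the second central moment tensor give the orientation,
and each semi-axis is `sqrt(5 λᵢ)`, the relation that holds exactly for a
solid ellipsoid. A small `pitch²/12` correction removes the within-voxel
moment. The fit is rotation-invariant and, on voxelised solid ellipsoids
with semi-axes 20–60 µm at the default voxel geometry, recovers semi-axes to
well under 1% (the acceptance suite measures this). An alternative
`mode = "extent"` (half the maximal extent along each principal axis) is
available for comparison.

Two interpretive choices are deliberate and flagged:

* the *envelope of the capillary tuft*, not Bowman's capsule, defines
  glomerular volume;
* per-animal aggregation is the arithmetic mean over the evaluated glomeruli
  (six per animal by convention), the animal being the unit of analysis.

## Segmentation

The positivity criterion behind "pixel counting" is never stated in
published FMA work, so the package makes it explicit and reproducible:
Otsu's threshold computed over the whole stack on the green channel
(via EBImage), with a fixed-threshold escape hatch. Every mask carries a
provenance record of the threshold value, the despeckling cutoff
(default 27 voxels ≈ one 3×3×3 clump, aimed at isolated microsphere
aggregates), and the connectivity used for component labelling (default 26;
labelling is lattice-based, while volumes are metric through the voxel
volume). ROI exclusion — the digital negative pen tool — is exact set
subtraction and records the excluded voxel count. ROIs can be supplied as
binary TIFF masks or as JSON per-slice polygons, rasterised with the
even-odd rule at pixel centres under a half-open edge convention (abutting
ROIs never double-count a pixel).

## The phantom generator

The generator emulates what the pipeline must cope with, with exact ground
truth recorded before any imaging degradation.

**Glomerular tuft.** Capillary loops are smooth closed curves confined to an
ellipsoidal envelope (default semi-axes 70 × 55 × 45 µm, giving an envelope
of ≈ 7.3 × 10⁵ µm³). Each loop is a radially modulated circle in a random
plane, warped smoothly through a common vascular-pole anchor, so the loop
set is guaranteed to be one connected network — loops enter and exit near
one pole, as afferent/efferent architecture does. Loops are added until the
lumen volume fraction reaches `target_density` (default 0.30); with the
default envelope this puts capillary volume near 2.2 × 10⁵ µm³, inside the
2–5 × 10⁵ µm³ range established for rat glomeruli by electron-microscopic
morphometry. Tube radii are drawn near 1.9 µm (lumen diameter ≈ 4 µm).

The radial placement of loops is the one genuinely free modelling choice
that affects validation: the moment-matched envelope fit is unbiased only if
lumen voxels fill the envelope like a solid ellipsoid (second moment a²/5
per axis). The loop base scale s is therefore drawn with density ∝ s⁴ on
[0.35, 0.95] — chosen from the closed-form moment calculation so that, after
the confinement clamp and pole warp, E[s²] lands at the solid-ellipsoid
value of 3/5 — and sampled with a stratified (Latin-hypercube style) stream
so the ensemble moment concentrates tightly even at a few dozen loops.

**Segmental dropout.** Disease-like capillary loss removes whole tube
segments (eighths of loops), never scattered voxels, mirroring segmental
obliteration by matrix accumulation. Removal uses exact incremental
unique-voxel accounting, so a requested dropout fraction is realised to
within one segment regardless of tube overlap, and removal sets at a fixed
seed are nested in the fraction (retained volume is monotone).

**Cortical plexus.** The peritubular compartment is an anastomotic network
of gently curving random-walk tubes filling the field to a target lumen
fraction (default 0.05), with optional embedded glomerular tufts whose ROI
masks are recorded to exercise exclusion.

**Imaging model.** The green channel is the lumen mask times a
multiplicative speckle field (smooth texture at 1.5 µm grain, contrast 0.25,
standing in for the granular appearance of sub-resolution microspheres —
individual 0.02 µm beads are far below voxel size, so texture is the
observable), convolved with an anisotropic Gaussian PSF, plus Gaussian
sensor noise, clipped to an 8-bit range. The PSF defaults
(σ<sub>xy</sub> = 0.35 µm, σ<sub>z</sub> = 0.6 µm) follow the diffraction
limit of a 0.75-NA confocal at 515 nm emission (lateral FWHM ≈ 0.8 µm,
axial ≈ 1.4 µm). The red channel is uniform parenchymal autofluorescence
outside the tuft, similarly blurred and noisy. All generators are pure
functions of parameters and seed.

**Presets.** `sham` is the healthy condition (no enlargement, no dropout);
`snx` emulates remnant-kidney morphology with tuft semi-axes × 1.4 and
dropout of 35% (tuft) / 50% (plexus). Because loops are generated to a
target density inside the *enlarged* envelope before dropout, the preset
reproduces the characteristic disease pattern: capillary volume rises
(hypertrophy outpaces dropout) while both densities fall. The presets encode
direction and plausible magnitude; they are modelling choices, not measured
values.

## What the phantoms do and do not show

Passing parameter-recovery tests on phantoms demonstrates that the
*computational* pipeline is correct and stable under realistic blur, speckle
and noise. It does not validate the wet-lab half of the method: incomplete
perfusion, bead clumping beyond speckle texture, vessel dilatation from
perfusate cooling, section compression and depth-dependent attenuation are
not modelled. Real-data conclusions inherit those caveats; between-group
comparisons are the intended use, as biases of this kind are shared across
groups.

## Sclerosis scoring and statistics

The glomerulosclerosis index takes per-glomerulus grades on the
conventional 0–4 scale (0 normal; 1, sclerotic area up to 25%; 2, 25–50%;
3, 50–75%; 4, 75–100%; 80 glomeruli per kidney by convention) and computes
the weighted severity index GSI = Σᵢ i·Fᵢ/100, where Fᵢ is the percentage of
glomeruli at grade i — linear in the distribution and bounded in [0, 4].
Grading itself is visual; the package accepts grades, it does not assign
them.

Group comparisons use the two-sided equal-variance Student's t-test (a
Welch option exists behind a flag). Skew-distributed, strictly positive
variables (proteinuria-like) are log-transformed before testing and
summarised as geometric mean ×/÷ tolerance factor, with the tolerance
factor defined as `exp(SEM of the natural logs)` — the multiplicative
analogue of mean ± SEM. That definition reproduces the conventional "×/÷"
presentation style but is an interpretation, and is flagged as such.

## The cohort driver

`run_cohort()` re-enacts a two-group study end to end: per animal it
generates six glomerular phantoms and one cortical field, runs the full
segmentation-and-morphometry pipeline, aggregates per-animal means, and
compares groups per endpoint. Every threshold, filter and fit parameter
actually applied is written to a structured log, and every random draw
derives from the single config seed, so a rerun is byte-identical.

Simulation sizes are a deliberate package choice: cohort phantoms are
miniaturised (tuft semi-axes scaled by 0.15, i.e. a ≈ 10.5 µm; cortical
fields of 32 × 64 × 64 voxels with one embedded tuft to exercise exclusion;
green channel only), which keeps a 10-animal cohort at a few seconds and
makes replicated power and null studies routine. Miniaturisation preserves the contrast structure (target
densities, enlargement and dropout factors are scale-free) at the cost of
coarser relative resolution; full-size phantoms are used wherever absolute
recovery accuracy is the question. Between-animal biological variability is
modelled as a 6% multiplicative log-normal jitter on target density and
(damped) on enlargement.

## Numerical choices and degenerate inputs

* Otsu thresholding refuses constant images and points to the fixed-threshold
  mode; fixed thresholds outside the dynamic range are rejected.
* The ellipsoid fit requires ≥ 4 non-coplanar foreground voxels and names
  the degeneracy (planar/collinear) otherwise.
* A capillary volume exceeding its envelope volume is treated as a
  mask/fit inconsistency and raised as an error, never clamped.
* Dropout at fraction 0 and 1 are exact identity and annihilation.
* The stained-area generator stops within 0.5 percentage points of its
  target and reports the exact realised fraction; unreachable targets error
  after a bounded number of attempts.
* Equality of volumes against the slice-wise summation oracle is asserted at
  10⁻¹² relative tolerance — the two summation orders differ only by
  floating-point association.
* Config validation reports all problems at once and fills documented
  defaults (including dz = 0.8141 µm).

## Known limitations

* The ellipsoid envelope is fitted to the closed lumen mask; a tuft whose
  capillaries systematically under-fill one pole will bias the envelope
  slightly (phantom validation bounds this at a few percent).
* Colour deconvolution uses the published haematoxylin/DAB vectors; results
  across stain batches are comparable only within a fixed configuration.
* No vesselness filtering, skeletonisation or network topology metrics are
  provided; the package quantifies volumes and densities only.
* TIFF support covers plain multi-page grayscale stacks with a JSON sidecar;
  proprietary microscope formats are out of scope.
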