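# fmaquant

Quantification of the renal microvasculature from fluorescent
microangiography (FMA) confocal z-stacks, for renal physiologists and image
analysts studying microvascular rarefaction in chronic kidney disease.

In FMA the vascular tree is perfused with agarose carrying fluorescent
microspheres, so perfused lumina — not endothelial antigens — delineate the
vessels in the green channel of a confocal z-stack (red carries tubular
autofluorescence). `fmaquant` turns such stacks into the study endpoints:

* **Glomerular capillary volume** by voxel counting: the positive pixel
  area of each optical section times the section spacing (Δz = 0.8141 µm by
  default), i.e. positive voxel count × voxel volume, exactly.
* **Glomerular volume** from a moment-matched ellipsoid fit of the tuft
  envelope, V = 4πabc/3 (semi-axis = √(5·eigenvalue) of the second moment
  tensor — exact for solid ellipsoids, rotation invariant).
* **Glomerular capillary density** = capillary volume / glomerular volume.
* **Peritubular capillary density**: lumen volume fraction of a cortical
  field with the glomerular tufts excluded (the digital negative pen tool).
* The conventional 2D comparator: **proportional immunostained area** per
  glomerular profile or cortical field, via colour deconvolution.
* **Glomerulosclerosis index** GSI = Σᵢ i·Fᵢ/100 over grades 0–4, and the
  study's group statistics (Student's t-test, log transformation for skewed
  variables, geometric mean ×/÷ tolerance factor).

Because no reference images exist for this modality, the package includes a
first-class **synthetic phantom generator** with exact ground truth —
capillary-loop tufts confined to ellipsoidal envelopes, an anastomotic
cortical plexus, segmental dropout, microsphere speckle, anisotropic PSF
blur and sensor noise — plus a cohort driver that re-enacts a sham vs
remnant-kidney (SNx) comparison end to end. See the methods vignette
(`vignettes/fma-quantification.Rmd`) for the model and its assumptions.

## Worked example

```r
library(fmaquant)

# A default glomerular phantom: 70 x 55 x 45 um tuft, target lumen
# fraction 0.30, realistic imaging degradation, known ground truth.
params  <- phantom_params(seed = 1)
phantom <- generate_glomerular_phantom(params)
phantom$truth$true_capillary_volume
#> [1] 219007.6

# Segment the green channel (Otsu threshold, recorded in provenance)
mask <- segment_vessels(phantom$stack, channel = "green", method = "otsu")
mask
#> vessel mask: 128 x 212 x 212 (z,y,x), 494259 positive voxels (8.59%)

# Full morphometry: capillary volume, envelope fit, density
metrics <- evaluate_glomeruli(phantom$stack, list(NULL))
metrics
#> microvascular metrics over 1 glomeruli:
#>   capillary volume : 2.144e+05 +/- 0 um^3
#>   glomerular volume: 7.02e+05 +/- 0 um^3
#>   capillary density: 0.305 +/- 0
phantom$truth$true_density
#> [1] 0.3017848
```

The measured capillary volume (2.14 × 10⁵ µm³) recovers the generator truth
(2.19 × 10⁵ µm³, inside the 2–5 × 10⁵ µm³ range reported for rat glomeruli)
within 2%, and the measured density 0.305 tracks the true 0.302.

A synthetic two-group cohort (5 animals per group, 6 glomeruli per animal
plus one cortical field each) reproduces the disease pattern — glomerular
volume and capillary volume up, both densities down in SNx:

```r
res <- run_cohort(list(seed = 1, groups = list(
  list(name = "sham", preset = "sham", n_animals = 5),
  list(name = "snx",  preset = "snx",  n_animals = 5))))
res
#> synthetic FMA cohort: 10 animals, 2 groups
#>   glomerular_volume              p = 9.513e-07 *
#>   glomerular_capillary_volume    p = 2.267e-06 *
#>   glomerular_capillary_density   p = 3.653e-08 *
#>   peritubular_capillary_density  p = 1.956e-08 *
aggregate(glomerular_capillary_density ~ group, res$measurements, mean)
#>   group glomerular_capillary_density
#> 1  sham                    0.4368810
#> 2   snx                    0.2562367
```

A thin command-line front-end over the same functions is provided at
`inst/cli/fma.R` (subcommands `phantom`, `segment`, `gsi`, `compare`,
`run`).

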