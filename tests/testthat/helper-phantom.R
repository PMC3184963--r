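# Small, fast phantom parameter sets used across tests. Tuft semi-axes and
# tube radius are miniaturised relative to the full-size defaults so that a
# phantom renders in well under a second.
small_glom_params <- function(seed = 1, ...) {
  phantom_params(kind = "glomerulus",
                 stack_shape = c(32, 56, 56),
                 tuft_semi_axes = c(14, 11, 9),
                 tube_radius_mean = 1.2, tube_radius_sd = 0.15,
                 seed = seed, ...)
}

small_cortex_params <- function(seed = 1, ...) {
  phantom_params(kind = "cortex",
                 stack_shape = c(32, 72, 72),
                 tube_radius_mean = 1.2, tube_radius_sd = 0.15,
                 seed = seed, ...)
}

# Independent per-slice oracle for voxel-counting volumetry: sum the positive
# pixel area of every optical section, times the section spacing.
slicewise_volume_oracle <- function(mask, geometry) {
  total <- 0
  for (z in seq_len(dim(mask)[1])) {
    area <- sum(mask[z, , ]) * geometry$dx * geometry$dy
    total <- total + area * geometry$dz
  }
  total
}

# Random blob-ish binary mask for property tests.
random_mask <- function(dims, p = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(prod(dims)) < p, dim = dims)
}
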