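test_that("phantom generation is a pure function of params and seed", {
  p <- small_glom_params(seed = 11)
  a <- generate_glomerular_phantom(p)
  b <- generate_glomerular_phantom(p)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$true_vessel_mask, b$truth$true_vessel_mask)
  expect_identical(a$truth$true_capillary_volume, b$truth$true_capillary_volume)
  c <- generate_glomerular_phantom(small_glom_params(seed = 12))
  expect_false(identical(a$stack$channels$green, c$stack$channels$green))
})

test_that("truth volumes are exact voxel-count bookkeeping", {
  ph <- generate_glomerular_phantom(small_glom_params(seed = 3))
  tr <- ph$truth
  g <- ph$stack$geometry
  expect_identical(tr$true_capillary_volume,
                   sum(tr$true_vessel_mask) * g$voxel_volume)
  expect_equal(tr$true_density,
               tr$true_capillary_volume / ellipsoid_volume(tr$true_tuft_ellipsoid))
  expect_true(tr$true_density > 0 && tr$true_density <= 1)
})

test_that("default-size tuft yields a capillary volume in the rat range", {
  ph <- generate_glomerular_phantom(phantom_params(seed = 5))
  v <- ph$truth$true_capillary_volume
  # rat glomerular capillary volume by EM morphometry: 2-5 x 10^5 um^3
  expect_gt(v, 2e5)
  expect_lt(v, 5e5)
  # and within the generator's requested density band
  expect_equal(ph$truth$true_density, 0.30, tolerance = 0.1)
})

test_that("segmental dropout removes the requested lumen fraction", {
  p0 <- small_glom_params(seed = 9, dropout_fraction = 0)
  v0 <- generate_glomerular_phantom(p0)$truth$true_capillary_volume
  for (f in c(0.3, 0.5)) {
    pf <- small_glom_params(seed = 9, dropout_fraction = f)
    vf <- generate_glomerular_phantom(pf)$truth$true_capillary_volume
    expect_equal(vf / v0, 1 - f, tolerance = 0.05 / (1 - f))
  }
})

test_that("dropout is identity at 0, annihilation at 1, monotone in between", {
  ph <- generate_glomerular_phantom(small_glom_params(seed = 4))
  vg <- ph$truth$geometry
  same <- apply_dropout(vg, 0, seed = 1)
  expect_identical(geometry_mask(same), geometry_mask(vg))
  none <- apply_dropout(vg, 1, seed = 1)
  expect_equal(sum(geometry_mask(none)), 0)
  counts <- vapply(c(0, 0.25, 0.5, 0.75),
                   function(f) sum(geometry_mask(apply_dropout(vg, f, seed = 7))),
                   numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("enlargement scales the truth ellipsoid volume exactly by f^3", {
  e1 <- generate_glomerular_phantom(small_glom_params(seed = 6))$truth$true_tuft_ellipsoid
  p2 <- phantom_params(kind = "glomerulus", stack_shape = c(48, 80, 80),
                       tuft_semi_axes = c(14, 11, 9), tube_radius_mean = 1.2,
                       tube_radius_sd = 0.15, enlargement_factor = 1.5, seed = 6)
  e2 <- generate_glomerular_phantom(p2)$truth$true_tuft_ellipsoid
  expect_equal(ellipsoid_volume(e2) / ellipsoid_volume(e1), 1.5^3)
})

test_that("a tuft larger than the stack is refused", {
  expect_error(generate_glomerular_phantom(
    phantom_params(stack_shape = c(16, 24, 24), tuft_semi_axes = c(30, 25, 20))),
    "does not fit")
})

test_that("cortex phantom hits the target plexus volume fraction", {
  ph <- generate_cortex_phantom(small_cortex_params(seed = 13, plexus_density = 0.05))
  expect_equal(ph$truth$plexus_density, 0.05, tolerance = 0.1)
  expect_true(abs(ph$truth$plexus_density - 0.05) < 0.005)
})

test_that("embedded glomeruli come with disjoint recorded ROI masks", {
  ph <- generate_cortex_phantom(small_cortex_params(seed = 14, n_glomeruli = 2),
                                glomerulus_semi_axes = c(8, 7, 6))
  rois <- ph$truth$glomerulus_rois
  expect_length(rois, 2)
  expect_equal(sum(rois[[1]] & rois[[2]]), 0)
  expect_length(ph$truth$glomerulus_volumes, 2)
})

test_that("cortex dropout reduces the network volume by the stated fraction", {
  v0 <- generate_cortex_phantom(small_cortex_params(seed = 15))$truth$plexus_volume
  v1 <- generate_cortex_phantom(
    small_cortex_params(seed = 15, dropout_fraction = 0.25))$truth$plexus_volume
  expect_equal(v1 / v0, 0.75, tolerance = 0.04)
})

test_that("degenerate imaging returns the scaled binary mask", {
  p <- small_glom_params(seed = 8, psf_sigma_xy = 0, psf_sigma_z = 0,
                         speckle_contrast = 0, noise_sd = 0,
                         vessel_intensity = 200)
  ph <- generate_glomerular_phantom(p)
  expect_identical(ph$stack$channels$green,
                   array(200 * as.numeric(ph$truth$true_vessel_mask),
                         dim = dim(ph$truth$true_vessel_mask)))
})

test_that("rendering is deterministic under a fixed seed", {
  p <- small_glom_params(seed = 2)
  m <- generate_glomerular_phantom(p)$truth$true_vessel_mask
  a <- render_imaging(m, p, seed = 99)
  b <- render_imaging(m, p, seed = 99)
  expect_identical(a$channels, b$channels)
  expect_error(render_imaging(m, small_glom_params(seed = 2, noise_sd = -1)),
               "non-negative")
})

test_that("synthetic IHC sections realise the stained-area target", {
  blank <- generate_ihc_section(0, c(64, 64), seed = 1)
  expect_equal(blank$truth_fraction, 0)
  expect_equal(sum(blank$stain_mask), 0)
  sec <- generate_ihc_section(0.12, c(256, 256), seed = 5)
  expect_true(sec$truth_fraction >= 0.115 && sec$truth_fraction <= 0.125)
  again <- generate_ihc_section(0.12, c(256, 256), seed = 5)
  expect_identical(sec$image, again$image)
  expect_error(generate_ihc_section(1.2, c(64, 64)), "\\[0, 1\\]")
})
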