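test_that("capillary volume equals the slice-wise summation oracle", {
  g <- voxel_geometry(0.73)
  for (s in 1:10) {
    m <- random_mask(c(16, 24, 24), p = runif(1, 0.05, 0.5), seed = s)
    vm <- vessel_mask(m, g)
    expect_equal(capillary_volume(vm), slicewise_volume_oracle(m, g),
                 tolerance = 1e-12)
  }
  # direct product example: 1000 voxels at the default pitches
  m <- array(FALSE, dim = c(10, 10, 10)); m[1:1000] <- TRUE
  expect_equal(capillary_volume(vessel_mask(m, g)), 1000 * 0.73 * 0.73 * 0.8141)
  expect_equal(capillary_volume(vessel_mask(array(FALSE, c(4, 4, 4)), g)), 0)
})

test_that("moment fit recovers a voxelised sphere within 3%", {
  g <- voxel_geometry(0.73)
  dims <- c(90, 100, 100)
  e <- ellipsoid(30, 30, 30, center = c(dims[1] * 0.8141, dims[2] * 0.73,
                                        dims[3] * 0.73) / 2)
  m <- fmaquant:::ellipsoid_mask(e, dims, g)
  f <- fit_ellipsoid(m, g)
  expect_equal(f$a, 30, tolerance = 0.03)
  expect_equal(f$c, 30, tolerance = 0.03)
})

test_that("moment fit recovers axis-aligned and rotated ellipsoids within 5%", {
  g <- voxel_geometry(0.73)
  dims <- c(120, 130, 130)
  ctr <- c(dims[1] * 0.8141, dims[2] * 0.73, dims[3] * 0.73) / 2
  e <- ellipsoid(40, 30, 20, center = ctr)
  f <- fit_ellipsoid(fmaquant:::ellipsoid_mask(e, dims, g), g)
  expect_equal(c(f$a, f$b, f$c), c(40, 30, 20), tolerance = 0.05)
  er <- ellipsoid(40, 30, 20, center = ctr,
                  rotation = fmaquant:::rotation_about_z(30 * pi / 180))
  fr <- fit_ellipsoid(fmaquant:::ellipsoid_mask(er, dims, g), g)
  expect_equal(c(fr$a, fr$b, fr$c), c(40, 30, 20), tolerance = 0.05)
})

test_that("moment fit error shrinks as sphere resolution grows", {
  g <- voxel_geometry(1, 1, 1)
  errs <- vapply(c(10, 20, 40), function(r) {
    n <- 2 * r + 8
    e <- ellipsoid(r, r, r, center = c(n, n, n) / 2)
    f <- fit_ellipsoid(fmaquant:::ellipsoid_mask(e, c(n, n, n), g), g)
    abs(f$a - r) / r
  }, numeric(1))
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 0.01)
})

test_that("degenerate point sets are rejected", {
  g <- voxel_geometry(1, 1, 1)
  m <- array(FALSE, dim = c(5, 5, 5))
  m[3, 3, 1:4] <- TRUE                 # collinear
  expect_error(fit_ellipsoid(m, g), "degenerate")
  m2 <- array(FALSE, dim = c(5, 5, 5))
  m2[3, , ] <- TRUE                    # planar
  expect_error(fit_ellipsoid(m2, g), "degenerate")
  expect_error(fit_ellipsoid(array(FALSE, c(5, 5, 5)), g), "at least 4")
})

test_that("density is the quotient and rejects impossible inputs", {
  expect_equal(glomerular_capillary_density(4.1e5, 1.4e6), 0.2928571,
               tolerance = 1e-6)
  expect_equal(glomerular_capillary_density(0, 1e6), 0)
  expect_error(glomerular_capillary_density(2, 1), "exceeds")
  expect_error(glomerular_capillary_density(1, 0), "positive")
})

test_that("density times envelope volume reproduces capillary volume", {
  ph <- generate_glomerular_phantom(small_glom_params(seed = 31))
  vm <- filter_small_components(label_components(segment_vessels(ph$stack)), 27)
  cv <- capillary_volume(vm)
  env <- fit_ellipsoid(fmaquant:::close_mask(vm$mask, vm$geometry, 2), vm$geometry)
  gv <- ellipsoid_volume(env)
  d <- glomerular_capillary_density(cv, gv)
  expect_equal(d * gv, cv, tolerance = 1e-9)
})

test_that("peritubular density is the lumen volume fraction of the field", {
  g <- voxel_geometry(0.73)
  m <- array(FALSE, dim = c(10, 20, 20))
  m[, 1:1, 1:10] <- TRUE               # 100 of 4000 voxels
  vm <- vessel_mask(m, g)
  expect_equal(peritubular_capillary_density(vm), 100 / 4000)
  expect_equal(peritubular_capillary_density(
    vessel_mask(array(FALSE, dim = dim(m)), g)), 0)
  expect_error(peritubular_capillary_density(vm, array(FALSE, dim = dim(m))),
               "empty")
})

test_that("evaluate_glomeruli aggregates per-glomerulus metrics per animal", {
  ph <- generate_glomerular_phantom(small_glom_params(seed = 32))
  whole <- array(TRUE, dim = dim(ph$truth$true_vessel_mask))
  # six identical ROIs: the mean equals the per-glomerulus value, SEM 0
  mm <- evaluate_glomeruli(ph$stack, rep(list(whole), 6))
  expect_equal(mm$n_glomeruli_evaluated, 6)
  expect_equal(mm$summary$density_sem, 0)
  expect_equal(mm$summary$density, mm$per_glomerulus$density[1])
  # an empty ROI among six is excluded with a warning
  rois <- c(rep(list(whole), 5), list(array(FALSE, dim = dim(whole))))
  expect_warning(mm2 <- evaluate_glomeruli(ph$stack, rois), "excluded")
  expect_equal(mm2$n_glomeruli_evaluated, 5)
  expect_equal(mm2$n_glomeruli_skipped, 1)
  expect_error(evaluate_glomeruli(ph$stack, list()), "at least one")
})

test_that("pipeline density tracks phantom truth within 10% (sham preset)", {
  for (s in 1:5) {
    ph <- generate_glomerular_phantom(phantom_params(seed = 200 + s))
    mm <- evaluate_glomeruli(ph$stack, list(NULL))
    expect_equal(mm$summary$density, ph$truth$true_density, tolerance = 0.10)
  }
})
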