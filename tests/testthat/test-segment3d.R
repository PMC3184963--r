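test_that("a binary-rendered phantom segments to the exact truth mask", {
  p <- small_glom_params(seed = 21, psf_sigma_xy = 0, psf_sigma_z = 0,
                         speckle_contrast = 0, noise_sd = 0)
  ph <- generate_glomerular_phantom(p)
  vm <- segment_vessels(ph$stack)
  expect_identical(unname(vm$mask), unname(ph$truth$true_vessel_mask))
  expect_equal(dice_coefficient(vm$mask, ph$truth$true_vessel_mask), 1.0)
  expect_equal(vm$provenance[[1]]$method, "otsu")
  expect_true(is.finite(vm$provenance[[1]]$threshold))
})

test_that("segmentation contracts: channels, constant images, fixed thresholds", {
  g <- voxel_geometry(0.73)
  flat <- image_stack(list(green = array(0, dim = c(4, 8, 8))), g)
  expect_error(segment_vessels(flat, channel = "red"), "not present")
  expect_error(segment_vessels(flat), "fixed")
  vm <- segment_vessels(flat, method = "fixed", manual_threshold = 10)
  expect_equal(sum(vm$mask), 0)
  expect_error(segment_vessels(flat, method = "fixed", manual_threshold = 300),
               "dynamic range")
  expect_error(segment_vessels(flat, method = "fixed"), "manual_threshold")
})

test_that("thresholding a binary image below its maximum is idempotent", {
  g <- voxel_geometry(0.73)
  m <- random_mask(c(8, 12, 12), p = 0.3, seed = 1)
  st <- image_stack(list(green = array(200 * as.numeric(m), dim = dim(m))), g)
  for (thr in c(0, 50, 199)) {
    vm <- segment_vessels(st, method = "fixed", manual_threshold = thr)
    expect_identical(unname(vm$mask), unname(m))
  }
})

test_that("connected components honour the chosen connectivity", {
  g <- voxel_geometry(1, 1, 1)
  # two voxels sharing only a corner
  m <- array(FALSE, dim = c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  vm <- vessel_mask(m, g)
  expect_equal(label_components(vm, connectivity = 26)$n_components, 1)
  expect_equal(label_components(vm, connectivity = 6)$n_components, 2)
  # edge-sharing pair: connected at 18 and 26, not at 6
  m2 <- array(FALSE, dim = c(3, 3, 3))
  m2[1, 1, 1] <- TRUE; m2[1, 2, 2] <- TRUE
  vm2 <- vessel_mask(m2, g)
  expect_equal(label_components(vm2, connectivity = 18)$n_components, 1)
  expect_equal(label_components(vm2, connectivity = 6)$n_components, 2)
  # two well-separated tubes
  m3 <- array(FALSE, dim = c(4, 10, 10))
  m3[2, 2, 2:8] <- TRUE; m3[3, 8, 2:8] <- TRUE
  expect_equal(label_components(vessel_mask(m3, g))$n_components, 2)
  expect_error(label_components(vm, connectivity = 4), "connectivity")
})

test_that("a zero-dropout tuft is one connected component", {
  ph <- generate_glomerular_phantom(small_glom_params(seed = 22))
  lc <- label_components(ph$truth$true_vessel_mask)
  expect_equal(lc$n_components, 1)
})

test_that("component bookkeeping: label counts sum to the mask count", {
  for (s in 1:5) {
    m <- random_mask(c(10, 14, 14), p = 0.2, seed = s)
    lc <- label_components(vessel_mask(m, voxel_geometry(1)))
    expect_true(all(sort(unique(as.vector(lc$labels))) ==
                    c(0, seq_len(lc$n_components))))
    expect_equal(sum(lc$component_sizes), sum(m))
  }
})

test_that("small-component filtering keeps only components above the cutoff", {
  g <- voxel_geometry(1, 1, 1)
  m <- array(FALSE, dim = c(8, 16, 16))
  m[2:6, 2:11, 2:11] <- TRUE          # 500-voxel block
  m[8, 14, 14:16] <- TRUE             # 3-voxel speck
  lc <- label_components(vessel_mask(m, g))
  expect_equal(sort(lc$component_sizes), c(3, 500))
  kept <- filter_small_components(lc, 10)
  expect_equal(sum(kept$mask), 500)
  # min_voxels = 0 is the identity
  expect_identical(unname(filter_small_components(lc, 0)$mask), unname(m))
  # cutoff above the largest component empties the mask with a warning
  expect_warning(out <- filter_small_components(lc, 1000), "removed all")
  expect_equal(sum(out$mask), 0)
})

test_that("region exclusion is exact set subtraction", {
  g <- voxel_geometry(0.73)
  m <- random_mask(c(8, 12, 12), p = 0.3, seed = 42)
  vm <- vessel_mask(m, g)
  none <- array(FALSE, dim = dim(m))
  expect_identical(exclude_region(vm, none)$mask, m)
  all_roi <- array(TRUE, dim = dim(m))
  expect_equal(sum(exclude_region(vm, all_roi)$mask), 0)
  roi <- random_mask(c(8, 12, 12), p = 0.4, seed = 43)
  out <- exclude_region(vm, roi)
  expect_equal(sum(out$mask), sum(m) - sum(m & roi))
  expect_error(exclude_region(vm, array(FALSE, dim = c(8, 12, 13))), "shape")
})

test_that("excluding manifest ROIs from a cortex phantom leaves the plexus", {
  ph <- generate_cortex_phantom(small_cortex_params(seed = 23, n_glomeruli = 2),
                                glomerulus_semi_axes = c(8, 7, 6))
  vm <- filter_small_components(label_components(segment_vessels(ph$stack)), 27)
  out <- exclude_region(vm, Reduce(`|`, ph$truth$glomerulus_rois))
  expect_equal(capillary_volume(out), ph$truth$plexus_volume, tolerance = 0.05)
})

test_that("polygon ROIs rasterise with even-odd fill at pixel centres", {
  dims <- c(4, 20, 20)
  # 10x10 axis-aligned square on slice 2: exactly 100 pixel centres inside
  sq <- list(z = 2, vertices = rbind(c(5, 5), c(15, 5), c(15, 15), c(5, 15)))
  m <- roi_from_polygons(list(sq), dims)
  expect_equal(sum(m), 100)
  expect_equal(sum(m[2, , ]), 100)
  # right triangle with legs 10: pixel centres strictly inside number 45
  # (the hypotenuse band is excluded by the half-open convention)
  tri <- list(z = 1, vertices = rbind(c(5, 5), c(15, 5), c(5, 15)))
  mt <- roi_from_polygons(list(tri), dims)
  expect_equal(sum(mt), 45)
  expect_error(roi_from_polygons(list(list(z = 9, vertices = sq$vertices)), dims),
               "out of range")
  # JSON round trip
  d <- withr::local_tempdir()
  fp <- file.path(d, "rois.json")
  jsonlite::write_json(list(list(z = 2, vertices = list(c(5, 5), c(15, 5),
                                                        c(15, 15), c(5, 15)))),
                       fp, auto_unbox = TRUE, digits = NA)
  expect_equal(sum(read_roi_mask(fp, dims)), 100)
})
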