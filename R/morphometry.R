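#' Capillary volume by voxel counting
#'
#' The volumetric analogue of summing the positive pixel area of each optical
#' section and multiplying by the section spacing: total positive voxel count
#' times the voxel volume (dx * dy * dz), with exact integer counting.
#'
#' @param vm A [vessel_mask()].
#' @return Volume in um^3.
#' @export
capillary_volume <- function(vm) {
  stopifnot(inherits(vm, "vessel_mask"))
  if (is.null(vm$geometry)) stop("vessel mask carries no voxel geometry")
  sum(vm$mask) * vm$geometry$voxel_volume
}

# voxel-centre coordinates (um) of foreground voxels, n x 3 in (z, y, x)
mask_coordinates <- function(mask, geometry) {
  idx <- which(mask)
  ai <- arrayInd(idx, dim(mask))
  sweep(ai - 0.5, 2, geom_pitch(geometry), `*`)
}

#' Fit an ellipsoid to a voxel mask by moment matching
#'
#' Centre = centroid of foreground voxel positions (in um); orientation =
#' principal axes of their second central moment tensor; semi-axes from the
#' solid-ellipsoid moment relation (semi-axis = sqrt(5 * eigenvalue)). A
#' small diagonal correction (pitch^2 / 12) removes the within-voxel
#' contribution to the moments. The fit is rotation-invariant and unbiased
#' for solid ellipsoids.
#'
#' `mode = "extent"` instead takes half the maximal extent along each
#' principal axis, for comparison with the moment-matched estimate.
#'
#' @param x A [vessel_mask()], or a logical 3D array with `geometry` given.
#' @param geometry A [voxel_geometry()] (when `x` is a bare array).
#' @param mode `"moment"` (default) or `"extent"`.
#' @return An [ellipsoid()].
#' @export
fit_ellipsoid <- function(x, geometry = NULL, mode = c("moment", "extent")) {
  mode <- match.arg(mode)
  if (inherits(x, "vessel_mask")) {
    mask <- x$mask
    geometry <- x$geometry
  } else {
    mask <- x
    if (is.null(geometry)) stop("geometry required when fitting a bare array")
  }
  pts <- mask_coordinates(mask, geometry)
  if (nrow(pts) < 4)
    stop("ellipsoid fit needs at least 4 foreground voxels, got ", nrow(pts))
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  cov <- crossprod(cen) / nrow(cen)
  # subtract the second moment of a voxel about its own centre
  cov <- cov - diag(geom_pitch(geometry)^2) / 12
  eig <- eigen(cov, symmetric = TRUE)
  if (any(eig$values <= 1e-9))
    stop("degenerate voxel set (planar or collinear); cannot fit an ellipsoid")
  if (mode == "moment") {
    semi <- sqrt(5 * eig$values)
  } else {
    proj <- cen %*% eig$vectors
    semi <- apply(abs(proj), 2, max)
  }
  # eigen() returns column vectors; rows of the rotation are principal axes
  ellipsoid(semi[1], semi[2], semi[3], center = ctr, rotation = t(eig$vectors))
}

#' Glomerular capillary density
#'
#' The quotient of glomerular capillary volume and total glomerular volume.
#'
#' @param capillary_volume Capillary volume, um^3.
#' @param glomerular_volume Glomerular (envelope) volume, um^3.
#' @return Dimensionless density in `[0, 1]`.
#' @export
glomerular_capillary_density <- function(capillary_volume, glomerular_volume) {
  if (glomerular_volume <= 0) stop("glomerular volume must be positive")
  if (capillary_volume < 0) stop("capillary volume must be non-negative")
  if (capillary_volume > glomerular_volume)
    stop("capillary volume (", signif(capillary_volume, 4),
         ") exceeds glomerular volume (", signif(glomerular_volume, 4),
         "); the lumen mask and envelope fit are inconsistent")
  capillary_volume / glomerular_volume
}

#' Peritubular capillary density
#'
#' Lumen volume fraction of an evaluated tissue field, computed after the
#' glomerular tufts have been excluded from both the vessel mask and the
#' field (see [exclude_region()]).
#'
#' @param vm A [vessel_mask()] with glomerular ROIs already excluded.
#' @param field_mask Logical array of evaluated field voxels (same shape),
#'   likewise excluding glomerular ROIs. Default: the whole stack.
#' @return Dimensionless lumen volume fraction in `[0, 1]`.
#' @export
peritubular_capillary_density <- function(vm, field_mask = NULL) {
  stopifnot(inherits(vm, "vessel_mask"))
  if (is.null(field_mask)) field_mask <- array(TRUE, dim = dim(vm$mask))
  if (!identical(dim(field_mask), dim(vm$mask)))
    stop("field_mask shape does not match the vessel mask")
  nf <- sum(field_mask)
  if (nf == 0) stop("empty evaluation field")
  sum(vm$mask & field_mask) / nf
}

# Morphological closing with a metric ball (radius in um), used to turn the
# lumen mask into an approximate tuft envelope before the ellipsoid fit.
close_mask <- function(mask, geometry, radius_um) {
  if (radius_um <= 0) return(mask)
  pitch <- geom_pitch(geometry)
  half <- floor(radius_um / pitch)
  offs <- as.matrix(expand.grid(z = -half[1]:half[1],
                                y = -half[2]:half[2],
                                x = -half[3]:half[3]))
  d2 <- (offs[, 1] * pitch[1])^2 + (offs[, 2] * pitch[2])^2 +
        (offs[, 3] * pitch[3])^2
  offs <- offs[d2 <= radius_um^2, , drop = FALSE]
  dims <- as.integer(dim(mask))
  dil <- .morph_3d(as.logical(mask), dims, offs, TRUE)
  ero <- .morph_3d(dil, dims, offs, FALSE)
  array(ero, dim = dims)
}

#' Measure capillary volume, envelope volume and density for glomerular ROIs
#'
#' For each ROI: segment the stack, restrict the lumen mask to the ROI,
#' despeckle, count capillary volume; morphologically close the lumen mask
#' (metric ball, `closing_radius_um`) to approximate the tuft envelope, fit
#' the moment-matched ellipsoid and take its 4*pi*a*b*c/3 volume; density is
#' the quotient. Per-animal summary is the arithmetic mean with SEM across
#' glomeruli, the animal being the unit of analysis. ROIs with no positive
#' voxels are excluded from the means with a warning.
#'
#' @param stack An [image_stack()].
#' @param roi_list List of logical 3D arrays (one per glomerulus); use
#'   `list(NULL)` to evaluate the whole field as a single glomerulus.
#' @param channel,method,manual_threshold Passed to [segment_vessels()].
#' @param min_voxels Despeckling cutoff, see [filter_small_components()].
#' @param connectivity Component connectivity (default 26).
#' @param closing_radius_um Ball radius for envelope closing, um.
#' @param fit_mode Envelope fit mode, see [fit_ellipsoid()].
#' @return A `microvascular_metrics` object: per-glomerulus data frame
#'   (`capillary_volume`, `glomerular_volume`, `density`), per-animal means
#'   and SEMs, and `n_glomeruli_evaluated`.
#' @export
evaluate_glomeruli <- function(stack, roi_list,
                               channel = "green", method = "otsu",
                               manual_threshold = NULL,
                               min_voxels = 27, connectivity = 26,
                               closing_radius_um = 2, fit_mode = "moment") {
  stopifnot(inherits(stack, "fma_stack"))
  if (length(roi_list) < 1) stop("at least one ROI is required")
  vm_full <- segment_vessels(stack, channel = channel, method = method,
                             manual_threshold = manual_threshold)
  rows <- list()
  skipped <- 0L
  for (i in seq_along(roi_list)) {
    roi <- roi_list[[i]]
    m <- if (is.null(roi)) vm_full$mask else (vm_full$mask & roi)
    vm <- vessel_mask(m, stack$geometry, provenance = vm_full$provenance)
    if (min_voxels > 0) {
      lc <- label_components(vm, connectivity = connectivity)
      if (lc$n_components > 0)
        vm <- suppressWarnings(filter_small_components(lc, min_voxels))
    }
    if (sum(vm$mask) < 4) {
      warning("ROI ", i, " has no usable positive voxels; excluded from the mean")
      skipped <- skipped + 1L
      next
    }
    cv <- capillary_volume(vm)
    env_mask <- close_mask(vm$mask, stack$geometry, closing_radius_um)
    env <- fit_ellipsoid(env_mask, stack$geometry, mode = fit_mode)
    gv <- ellipsoid_volume(env)
    dens <- glomerular_capillary_density(cv, gv)
    rows[[length(rows) + 1L]] <-
      data.frame(roi = i, capillary_volume = cv, glomerular_volume = gv,
                 density = dens)
  }
  if (length(rows) == 0) stop("no ROI produced a measurable glomerulus")
  per_glom <- do.call(rbind, rows)
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  summary <- list(
    capillary_volume = mean(per_glom$capillary_volume),
    capillary_volume_sem = sem(per_glom$capillary_volume),
    glomerular_volume = mean(per_glom$glomerular_volume),
    glomerular_volume_sem = sem(per_glom$glomerular_volume),
    density = mean(per_glom$density),
    density_sem = sem(per_glom$density))
  structure(list(per_glomerulus = per_glom, summary = summary,
                 n_glomeruli_evaluated = nrow(per_glom),
                 n_glomeruli_skipped = skipped,
                 provenance = list(threshold = vm_full$provenance,
                                   min_voxels = min_voxels,
                                   connectivity = connectivity,
                                   closing_radius_um = closing_radius_um,
                                   fit_mode = fit_mode)),
            class = "microvascular_metrics")
}

#' @export
print.microvascular_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("microvascular metrics over %d glomeruli:\n", x$n_glomeruli_evaluated))
  cat(sprintf("  capillary volume : %.4g +/- %.3g um^3\n",
              s$capillary_volume, s$capillary_volume_sem))
  cat(sprintf("  glomerular volume: %.4g +/- %.3g um^3\n",
              s$glomerular_volume, s$glomerular_volume_sem))
  cat(sprintf("  capillary density: %.3f +/- %.3g\n", s$density, s$density_sem))
  invisible(x)
}
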