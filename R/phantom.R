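#' Parameters for synthetic FMA phantoms
#'
#' Describes a synthetic two-channel confocal stack of microsphere-perfused
#' kidney tissue with known ground truth. `kind = "glomerulus"` builds a
#' single capillary tuft: smooth capillary loops entering and exiting near a
#' vascular pole, confined to an ellipsoidal envelope. `kind = "cortex"`
#' builds an anastomotic intertubular plexus at a target lumen volume
#' fraction, optionally with embedded glomerular tufts and their ROI masks.
#'
#' Loops are added until the tuft's lumen volume fraction reaches
#' `target_density`; set `target_density = NULL` to draw exactly `n_loops`
#' loops instead. Default tuft semi-axes (70, 55, 45) um give an envelope
#' volume of about 7.3e5 um^3, so the default capillary volume (~2.2e5 um^3)
#' falls inside the 2-5e5 um^3 range reported for rat glomeruli by electron
#' microscopic morphometry.
#'
#' @param kind `"glomerulus"` or `"cortex"`.
#' @param stack_shape Stack dimensions `(z, y, x)` in voxels; `NULL` sizes the
#'   stack to fit the tuft with margin (glomerulus) or uses `(64, 160, 160)`
#'   (cortex).
#' @param voxel_xy Lateral pixel pitch, um/pixel (default 0.73, typical for a
#'   20x objective at zoom 2; always recorded in metadata).
#' @param voxel_z Axial step, um (default 0.8141).
#' @param tuft_semi_axes Tuft envelope semi-axes `(a, b, c)` in um.
#' @param n_loops Number of capillary loops when `target_density` is `NULL`.
#' @param target_density Target lumen volume fraction of the tuft envelope.
#' @param tube_radius_mean,tube_radius_sd Capillary lumen radius, um.
#' @param dropout_fraction Fraction of lumen volume removed segmentally.
#' @param enlargement_factor Multiplier on tuft semi-axes (hypertrophy).
#' @param plexus_density Target lumen volume fraction for the cortex plexus.
#' @param n_glomeruli Glomerular tufts embedded in a cortex field.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas, um. Defaults follow
#'   the diffraction limit of a 0.75-NA confocal at 515 nm emission (lateral
#'   FWHM ~0.8 um, axial ~1.4 um).
#' @param speckle_grain Grain scale of the multiplicative microsphere speckle
#'   texture, um.
#' @param speckle_contrast Relative amplitude of the speckle texture.
#' @param autofluorescence_level Red-channel parenchymal intensity.
#' @param noise_sd Additive Gaussian sensor noise SD, intensity units.
#' @param vessel_intensity Green-channel lumen intensity before degradation;
#'   `NULL` = 80% of the dynamic range.
#' @param bit_depth 8 or 16.
#' @param render_red Render the red (autofluorescence) channel; set `FALSE`
#'   to produce a green-only stack when only lumen measurements are needed.
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical output.
#' @param pole_sigma Angular width (radians) of each loop's approach to the
#'   common vascular-pole anchor; every loop passes through the anchor, which
#'   keeps the tuft a single connected network.
#' @param loop_segments Arcs per loop used as the unit of segmental dropout.
#' @param max_loops Bound on loop/segment generation attempts.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(kind = c("glomerulus", "cortex"),
                           stack_shape = NULL,
                           voxel_xy = 0.73, voxel_z = 0.8141,
                           tuft_semi_axes = c(70, 55, 45),
                           n_loops = NULL, target_density = 0.30,
                           tube_radius_mean = 1.9, tube_radius_sd = 0.25,
                           dropout_fraction = 0, enlargement_factor = 1,
                           plexus_density = 0.05, n_glomeruli = 0,
                           psf_sigma_xy = 0.35, psf_sigma_z = 0.6,
                           speckle_grain = 1.5, speckle_contrast = 0.25,
                           autofluorescence_level = 40, noise_sd = 6,
                           vessel_intensity = NULL, bit_depth = 8,
                           render_red = TRUE,
                           seed = 1L,
                           pole_sigma = 0.6, loop_segments = 8,
                           max_loops = 4000) {
  kind <- match.arg(kind)
  lens <- c(voxel_xy = voxel_xy, voxel_z = voxel_z,
            tube_radius_mean = tube_radius_mean, tuft = tuft_semi_axes,
            speckle_grain = speckle_grain)
  if (any(lens <= 0)) stop("all length scales must be strictly positive")
  if (dropout_fraction < 0 || dropout_fraction > 1)
    stop("dropout_fraction must be in [0, 1]")
  if (enlargement_factor <= 0) stop("enlargement_factor must be > 0")
  if (psf_sigma_xy < 0 || psf_sigma_z < 0 || noise_sd < 0 || tube_radius_sd < 0)
    stop("PSF sigmas, noise_sd and tube_radius_sd must be non-negative")
  if (!is.null(target_density) &&
      (target_density <= 0 || target_density >= 1))
    stop("target_density must be in (0, 1)")
  if (plexus_density <= 0 || plexus_density >= 1)
    stop("plexus_density must be in (0, 1)")
  if (is.null(stack_shape)) {
    if (kind == "glomerulus") {
      f <- enlargement_factor
      a <- tuft_semi_axes[1] * f; cc <- tuft_semi_axes[3] * f
      margin <- 2 * tube_radius_mean + 2.5
      nx <- ceiling(2 * (a + margin) / voxel_xy / 4) * 4
      nz <- ceiling(2 * (cc + margin) / voxel_z / 4) * 4
      stack_shape <- c(nz, nx, nx)
    } else {
      stack_shape <- c(96, 160, 160)
    }
  }
  stack_shape <- as.integer(stack_shape)
  stopifnot(length(stack_shape) == 3, all(stack_shape >= 8))
  p <- list(kind = kind, stack_shape = stack_shape,
            voxel_xy = voxel_xy, voxel_z = voxel_z,
            tuft_semi_axes = tuft_semi_axes,
            n_loops = n_loops, target_density = target_density,
            tube_radius_mean = tube_radius_mean, tube_radius_sd = tube_radius_sd,
            dropout_fraction = dropout_fraction,
            enlargement_factor = enlargement_factor,
            plexus_density = plexus_density, n_glomeruli = n_glomeruli,
            psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
            speckle_grain = speckle_grain, speckle_contrast = speckle_contrast,
            autofluorescence_level = autofluorescence_level,
            noise_sd = noise_sd, vessel_intensity = vessel_intensity,
            bit_depth = as.integer(bit_depth), render_red = isTRUE(render_red),
            seed = as.integer(seed),
            pole_sigma = pole_sigma, loop_segments = loop_segments,
            max_loops = max_loops)
  class(p) <- "phantom_params"
  p
}

#' Preset phantom parameter sets for the two study-like conditions
#'
#' `"sham"` is the healthy control condition (no enlargement, no dropout).
#' `"snx"` emulates remnant-kidney morphology: glomerular hypertrophy
#' (semi-axes x 1.4) with segmental capillary dropout (35% in the tuft, 50%
#' in the cortical plexus). The presets encode the direction and approximate
#' magnitude of the disease contrast; they are modelling choices, not
#' measured values.
#'
#' @param preset `"sham"` or `"snx"`.
#' @param kind `"glomerulus"` or `"cortex"`.
#' @param ... Overrides passed to [phantom_params()].
#' @return A `phantom_params` list.
#' @export
phantom_preset <- function(preset = c("sham", "snx"),
                           kind = c("glomerulus", "cortex"), ...) {
  preset <- match.arg(preset)
  kind <- match.arg(kind)
  args <- if (preset == "sham") {
    list(kind = kind, enlargement_factor = 1, dropout_fraction = 0)
  } else {
    list(kind = kind, enlargement_factor = 1.4,
         dropout_fraction = if (kind == "glomerulus") 0.35 else 0.5)
  }
  args <- utils::modifyList(args, list(...))
  do.call(phantom_params, args)
}

# ---------------------------------------------------------------------------
# Vessel geometry: a set of tube segments plus their rasterised voxel ids.

vessel_geometry_obj <- function(segments, voxel_ids, dims, vox_geom) {
  structure(list(segments = segments, voxel_ids = voxel_ids,
                 dims = dims, vox_geom = vox_geom),
            class = "vessel_geometry")
}

#' Binary mask of a vessel geometry
#'
#' @param vg A `vessel_geometry` (see [apply_dropout()]).
#' @return Logical 3D array in `(z, y, x)` order.
#' @export
geometry_mask <- function(vg) {
  stopifnot(inherits(vg, "vessel_geometry"))
  m <- logical(prod(vg$dims))
  for (ids in vg$voxel_ids) m[ids] <- TRUE
  array(m, dim = vg$dims)
}

geometry_voxel_count <- function(vg) {
  if (length(vg$voxel_ids) == 0) return(0L)
  length(unique(unlist(vg$voxel_ids, use.names = FALSE)))
}

#' Segmental capillary dropout
#'
#' Removes whole tube segments (never scattered voxels) until the removed
#' unique lumen volume reaches the requested fraction, mimicking the
#' segmental capillary loss of glomerulosclerosis. Uses exact incremental
#' unique-voxel accounting so the realised fraction matches the request to
#' within one segment even where tubes overlap. At a fixed seed the removed
#' sets are nested in `fraction`, so retained volume is non-increasing.
#'
#' @param vg A `vessel_geometry`.
#' @param fraction Fraction of lumen volume to remove, in `[0, 1]`.
#' @param seed Integer seed for the removal order.
#' @return A `vessel_geometry` with the retained segments; attribute
#'   `dropout_realized` records the achieved removed fraction.
#' @export
apply_dropout <- function(vg, fraction, seed = NULL) {
  stopifnot(inherits(vg, "vessel_geometry"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- length(vg$segments)
  if (fraction == 0 || n == 0) {
    out <- vg
    attr(out, "dropout_realized") <- 0
    return(out)
  }
  if (fraction == 1) {
    out <- vessel_geometry_obj(list(), list(), vg$dims, vg$vox_geom)
    attr(out, "dropout_realized") <- 1
    return(out)
  }
  with_seed(seed, {
    mult <- integer(prod(vg$dims))
    for (ids in vg$voxel_ids) mult[ids] <- mult[ids] + 1L
    total <- sum(mult > 0L)
    target <- fraction * total
    ord <- sample.int(n)
    removed <- 0
    drop_flag <- logical(n)
    for (k in ord) {
      ids <- vg$voxel_ids[[k]]
      gain <- sum(mult[ids] == 1L)
      # accept removal only while it brings us closer to the target
      if (abs(removed + gain - target) <= abs(removed - target)) {
        drop_flag[k] <- TRUE
        mult[ids] <- mult[ids] - 1L
        removed <- removed + gain
      }
      if (removed >= target) break
    }
    keep <- !drop_flag
    out <- vessel_geometry_obj(vg$segments[keep], vg$voxel_ids[keep],
                               vg$dims, vg$vox_geom)
    attr(out, "dropout_realized") <- removed / total
    out
  })
}

# ---------------------------------------------------------------------------
# Loop construction (normalised ellipsoid frame)

# One capillary loop: a radially modulated circle in a random plane, warped
# smoothly so it passes through a common vascular-pole anchor. The warp makes
# every loop intersect a small pole region, guaranteeing a connected loop set
# (afferent/efferent architecture); the anchor is on the shortest principal
# axis. The base scale s is drawn with density proportional to s^3 on
# [0.35, 0.95], which after the clamp and warp leaves lumen voxels with
# approximately the second moments of a solid ellipsoid (E[s^2] ~ 3/5),
# keeping the moment-matched envelope fit near-unbiased. `pole_sigma` (radians) sets how localised the pole approach
# is along the loop.
make_loop_points <- function(semi, pole_anchor, step_um, pole_sigma = 0.6,
                             s_unif = NULL) {
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  w <- rnorm(3)
  v <- w - sum(w * u) * u
  v <- v / sqrt(sum(v^2))
  if (is.null(s_unif)) s_unif <- runif(1)
  s <- (s_unif * (0.95^5 - 0.35^5) + 0.35^5)^(1 / 5)
  a1 <- runif(1, 0, 0.12); a2 <- runif(1, 0, 0.12)
  p1 <- runif(1, 0, 2 * pi); p2 <- runif(1, 0, 2 * pi)
  circ <- 2 * pi * s * mean(semi)
  npts <- max(32L, ceiling(circ / step_um))
  th <- seq(0, 2 * pi, length.out = npts + 1L)[-(npts + 1L)]
  mod <- 1 + a1 * sin(th + p1) + a2 * sin(2 * th + p2)
  base <- outer(cos(th), u) + outer(sin(th), v)   # npts x 3, unit circle
  pts <- base * (s * mod)                          # normalised coordinates
  # warp the theta ~ 0 neighbourhood through the pole anchor
  ang <- pmin(th, 2 * pi - th)                     # angular distance to theta 0
  wgt <- exp(-(ang / pole_sigma)^2)
  pts <- pts + outer(wgt, pole_anchor - pts[1, ])
  nrm <- sqrt(rowSums(pts^2))
  over <- nrm > 0.95
  if (any(over)) pts[over, ] <- pts[over, ] * (0.95 / nrm[over])
  pts
}

# Stratified (Latin-hypercube style) uniform stream for the loop base scale:
# each block of `k` draws covers all strata once in shuffled order, so the
# loop ensemble's radial second moment concentrates tightly around its
# expectation even for a few dozen loops.
stratified_unif_stream <- function(k = 16L) {
  strata <- sample.int(k)
  i <- 0L
  function() {
    i <<- i + 1L
    j <- (i - 1L) %% k + 1L
    if (j == 1L && i > 1L) strata <<- sample.int(k)
    (strata[j] - runif(1)) / k
  }
}

# Split the closed loop point sequence into `nseg` contiguous arcs (the unit
# of segmental dropout), each overlapping its neighbour by one point so the
# rasterised tube stays gap-free.
split_loop <- function(pts, nseg) {
  n <- nrow(pts)
  bounds <- round(seq(1, n + 1, length.out = nseg + 1))
  lapply(seq_len(nseg), function(i) {
    idx <- bounds[i]:min(bounds[i + 1], n + 1)
    idx[idx > n] <- idx[idx > n] - n   # wrap to close the loop
    pts[idx, , drop = FALSE]
  })
}

# Map normalised principal-frame points to stack-frame micrometres.
frame_to_stack <- function(pts_norm, semi, rotation, centre) {
  scaled <- sweep(pts_norm, 2, semi, `*`)
  # rotation rows are principal axes in stack (z,y,x) coordinates; points are
  # in (axis1, axis2, axis3) order
  sweep(scaled %*% rotation, 2, centre, `+`)
}

truncnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(max(lo, min(hi, mean)))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# ---------------------------------------------------------------------------

#' Generate a glomerular FMA phantom
#'
#' Builds a capillary-loop tuft confined to an ellipsoidal envelope, applies
#' segmental dropout, and renders a two-channel stack (green: microsphere
#' fluorescence in the lumina; red: tubular autofluorescence outside the
#' tuft) through the imaging model of [render_imaging()]. The returned truth
#' manifest records the clean pre-degradation lumen mask, the exact capillary
#' volume (voxel count x voxel volume), the confinement ellipsoid and the
#' true density.
#'
#' @param params A [phantom_params()] with `kind = "glomerulus"`.
#' @return A list with elements `stack` ([image_stack()]) and `truth`
#'   (`phantom_truth`).
#' @export
generate_glomerular_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  if (params$kind != "glomerulus") stop("params$kind must be 'glomerulus'")
  dims <- params$stack_shape
  geom <- voxel_geometry(params$voxel_xy, params$voxel_xy, params$voxel_z)
  semi <- params$tuft_semi_axes * params$enlargement_factor
  half <- c(dims[1] * geom$dz, dims[2] * geom$dy, dims[3] * geom$dx) / 2
  margin <- 2 * params$tube_radius_mean
  # orientation is a rotation about stack z, so axis extents are bounded by
  # (c) axially and (a) laterally
  if (semi[3] + margin > half[1] || semi[1] + margin > half[2] ||
      semi[1] + margin > half[3])
    stop("tuft (semi-axes ", paste(round(semi, 1), collapse = "x"),
         " um) does not fit in the stack with a 2-tube-radius margin")
  with_seed(params$seed, {
    rot <- rotation_about_z(runif(1, 0, 2 * pi))
    centre <- half   # tuft centred in the stack
    tuft <- ellipsoid(semi[1], semi[2], semi[3], center = centre, rotation = rot)
    v_ell <- ellipsoid_volume(tuft)
    step_um <- min(geom_pitch(geom)) / 2
    pitch <- geom_pitch(geom)
    pole_anchor <- c(0, 0, 0.8)   # vascular pole on the shortest axis
    segments <- list(); voxel_ids <- list()
    mult <- integer(prod(dims))
    covered <- 0L
    target_vox <- if (!is.null(params$target_density))
      params$target_density * v_ell / geom$voxel_volume else Inf
    n_target_loops <- if (is.null(params$target_density)) {
      if (is.null(params$n_loops)) stop("either target_density or n_loops must be set")
      params$n_loops
    } else Inf
    next_s <- stratified_unif_stream()
    loops <- 0L
    while (loops < n_target_loops && covered < target_vox) {
      if (loops >= params$max_loops)
        stop("requested target_density ", params$target_density,
             " unreachable within max_loops = ", params$max_loops,
             " capillary loops")
      loops <- loops + 1L
      r <- truncnorm1(params$tube_radius_mean, params$tube_radius_sd,
                      params$tube_radius_mean / 2, params$tube_radius_mean * 2)
      # keep the tube inside the envelope: shrink the path so centreline
      # norm + tube radius stays within the ellipsoid
      smax <- max(0.2, 1 - r / min(semi))
      pts <- make_loop_points(semi, pole_anchor, step_um, params$pole_sigma,
                              s_unif = next_s())
      nrm <- sqrt(rowSums(pts^2))
      over <- nrm > smax
      if (any(over)) pts[over, ] <- pts[over, ] * (smax / nrm[over])
      arcs <- split_loop(pts, params$loop_segments)
      for (arc in arcs) {
        stack_pts <- frame_to_stack(arc, semi, rot, centre)
        ids <- .raster_tube(stack_pts, r, as.integer(dims), pitch)
        if (length(ids) == 0) next
        segments[[length(segments) + 1L]] <- list(radius = r, n_points = nrow(arc))
        voxel_ids[[length(voxel_ids) + 1L]] <- ids
        covered <- covered + sum(mult[ids] == 0L)
        mult[ids] <- mult[ids] + 1L
      }
    }
    vg <- vessel_geometry_obj(segments, voxel_ids, dims, geom)
    drop_seed <- sample.int(.Machine$integer.max - 1L, 1)
    vg_post <- apply_dropout(vg, params$dropout_fraction, seed = drop_seed)
    true_mask <- geometry_mask(vg_post)
    n_vox <- sum(true_mask)
    true_volume <- n_vox * geom$voxel_volume
    bg <- if (isTRUE(params$render_red)) !ellipsoid_mask(tuft, dims, geom) else NULL
    render_seed <- sample.int(.Machine$integer.max - 1L, 1)
    stack <- render_imaging(true_mask, params, background_mask = bg,
                            seed = render_seed, geometry = geom)
    truth <- structure(list(
      true_vessel_mask = true_mask,
      true_capillary_volume = true_volume,
      true_tuft_ellipsoid = tuft,
      true_density = true_volume / v_ell,
      dropout_applied = attr(vg_post, "dropout_realized"),
      n_loops_used = loops,
      geometry = vg_post,
      glomerulus_rois = NULL,
      seed = params$seed,
      params = params), class = "phantom_truth")
    list(stack = stack, truth = truth)
  })
}

#' Generate a cortical-plexus FMA phantom
#'
#' Fills the field with an anastomotic random tube network at the target
#' lumen volume fraction, optionally embedding glomerular tufts whose ROI
#' masks are recorded in the truth manifest (to exercise tuft exclusion, the
#' digital analogue of the negative pen tool). Dropout applies to the plexus.
#'
#' @param params A [phantom_params()] with `kind = "cortex"`.
#' @param glomerulus_semi_axes Semi-axes of embedded tufts, um.
#' @return A list with elements `stack` and `truth`; the truth manifest
#'   includes `glomerulus_rois` (list of logical arrays), `plexus_volume` and
#'   per-glomerulus capillary volumes.
#' @export
generate_cortex_phantom <- function(params, glomerulus_semi_axes = c(22, 18, 15)) {
  stopifnot(inherits(params, "phantom_params"))
  if (params$kind != "cortex") stop("params$kind must be 'cortex'")
  dims <- params$stack_shape
  geom <- voxel_geometry(params$voxel_xy, params$voxel_xy, params$voxel_z)
  pitch <- geom_pitch(geom)
  extent <- dims * pitch           # (z, y, x) um
  with_seed(params$seed, {
    # --- embedded glomerular tufts -------------------------------------
    gl_semi <- glomerulus_semi_axes * params$enlargement_factor
    rois <- list(); tufts <- list()
    occupied <- NULL
    if (params$n_glomeruli > 0) {
      pad <- max(gl_semi) + 3
      if (any(2 * pad > extent))
        stop("embedded glomeruli do not fit in the cortex field")
      # rejection placement of disjoint ROIs; restart the whole set if a
      # placement deadlocks, error after bounded restarts
      placed <- FALSE
      for (restart in 1:40) {
        tufts <- list(); rois <- list(); occupied <- NULL
        tries <- 0
        while (length(tufts) < params$n_glomeruli && tries < 60) {
          tries <- tries + 1
          cand <- c(runif(1, pad, extent[1] - pad),
                    runif(1, pad, extent[2] - pad),
                    runif(1, pad, extent[3] - pad))
          rot <- rotation_about_z(runif(1, 0, 2 * pi))
          roi <- ellipsoid(gl_semi[1] + 2, gl_semi[2] + 2, gl_semi[3] + 2,
                           center = cand, rotation = rot)
          roi_mask <- ellipsoid_mask(roi, dims, geom)
          if (!is.null(occupied) && any(roi_mask & occupied)) next
          tufts[[length(tufts) + 1L]] <-
            ellipsoid(gl_semi[1], gl_semi[2], gl_semi[3],
                      center = cand, rotation = rot)
          rois[[length(rois) + 1L]] <- roi_mask
          occupied <- if (is.null(occupied)) roi_mask else (occupied | roi_mask)
        }
        if (length(tufts) == params$n_glomeruli) { placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place ", params$n_glomeruli,
             " non-overlapping glomeruli after 40 placement restarts")
    }
    roi_vox <- if (is.null(occupied)) 0L else sum(occupied)
    field_vox <- prod(dims) - roi_vox
    # --- glomerular loops inside embedded tufts ------------------------
    gl_ids <- list(); gl_volumes <- numeric(0)
    step_um <- min(pitch) / 2
    pole_anchor <- c(0, 0, 0.8)
    for (i in seq_along(tufts)) {
      tuft <- tufts[[i]]
      semi <- c(tuft$a, tuft$b, tuft$c)
      v_ell <- ellipsoid_volume(tuft)
      tgt <- 0.30 * v_ell / geom$voxel_volume
      mult <- integer(prod(dims)); covered <- 0L; loops <- 0L
      ids_i <- integer(0)
      next_s <- stratified_unif_stream()
      while (covered < tgt && loops < params$max_loops) {
        loops <- loops + 1L
        r <- truncnorm1(params$tube_radius_mean, params$tube_radius_sd,
                        params$tube_radius_mean / 2, params$tube_radius_mean * 2)
        smax <- max(0.2, 1 - r / min(semi))
        pts <- make_loop_points(semi, pole_anchor, step_um, params$pole_sigma,
                                s_unif = next_s())
        nrm <- sqrt(rowSums(pts^2)); over <- nrm > smax
        if (any(over)) pts[over, ] <- pts[over, ] * (smax / nrm[over])
        sp <- frame_to_stack(pts, semi, tuft$rotation, tuft$center)
        ids <- .raster_tube(sp, r, as.integer(dims), pitch)
        covered <- covered + sum(mult[ids] == 0L)
        mult[ids] <- mult[ids] + 1L
        ids_i <- c(ids_i, ids)
      }
      gl_ids[[i]] <- unique(ids_i)
      gl_volumes[i] <- length(gl_ids[[i]]) * geom$voxel_volume
    }
    # --- anastomotic plexus --------------------------------------------
    segments <- list(); voxel_ids <- list()
    mult <- integer(prod(dims)); covered <- 0L
    target_vox <- params$plexus_density * field_vox
    occ_idx <- if (is.null(occupied)) integer(0) else which(occupied)
    occ_flag <- logical(prod(dims)); occ_flag[occ_idx] <- TRUE
    n_seg <- 0L
    while (covered < target_vox) {
      n_seg <- n_seg + 1L
      if (n_seg > params$max_loops * 4)
        stop("requested plexus_density ", params$plexus_density,
             " unreachable within segment budget")
      r <- truncnorm1(params$tube_radius_mean, params$tube_radius_sd,
                      params$tube_radius_mean / 2, params$tube_radius_mean * 2)
      len <- runif(1, 30, 80)
      npts <- ceiling(len / step_um)
      p0 <- c(runif(1, r, extent[1] - r), runif(1, r, extent[2] - r),
              runif(1, r, extent[3] - r))
      # smooth random-walk centreline: direction drifts by accumulated
      # Gaussian increments, renormalised, giving gently curving tubes
      d0 <- rnorm(3); d0 <- d0 / sqrt(sum(d0^2))
      W <- matrix(rnorm((npts - 1) * 3, 0, 0.08), npts - 1, 3)
      D <- sweep(apply(W, 2, cumsum), 2, d0, `+`)
      D <- D / sqrt(rowSums(D^2))
      pts <- rbind(p0, sweep(apply(D * step_um, 2, cumsum), 2, p0, `+`))
      inside <- pts[, 1] > r & pts[, 1] < extent[1] - r &
                pts[, 2] > r & pts[, 2] < extent[2] - r &
                pts[, 3] > r & pts[, 3] < extent[3] - r
      if (!any(inside)) next
      last <- which(!inside)[1]
      if (!is.na(last)) { if (last == 1) next; pts <- pts[1:(last - 1), , drop = FALSE] }
      ids <- .raster_tube(pts, r, as.integer(dims), pitch)
      ids <- ids[!occ_flag[ids]]      # plexus stays outside glomerular ROIs
      if (length(ids) == 0) next
      segments[[length(segments) + 1L]] <- list(radius = r, n_points = nrow(pts))
      voxel_ids[[length(voxel_ids) + 1L]] <- ids
      covered <- covered + sum(mult[ids] == 0L)
      mult[ids] <- mult[ids] + 1L
    }
    vg <- vessel_geometry_obj(segments, voxel_ids, dims, geom)
    drop_seed <- sample.int(.Machine$integer.max - 1L, 1)
    vg_post <- apply_dropout(vg, params$dropout_fraction, seed = drop_seed)
    plexus_mask <- geometry_mask(vg_post)
    plexus_volume <- sum(plexus_mask) * geom$voxel_volume
    true_mask <- plexus_mask
    for (ids in gl_ids) true_mask[ids] <- TRUE
    true_volume <- sum(true_mask) * geom$voxel_volume
    bg <- !true_mask
    if (!is.null(occupied)) bg <- bg & !occupied
    render_seed <- sample.int(.Machine$integer.max - 1L, 1)
    stack <- render_imaging(true_mask, params, background_mask = bg,
                            seed = render_seed, geometry = geom)
    truth <- structure(list(
      true_vessel_mask = true_mask,
      true_capillary_volume = true_volume,
      plexus_volume = plexus_volume,
      plexus_density = plexus_volume / (field_vox * geom$voxel_volume),
      glomerulus_volumes = gl_volumes,
      glomerulus_rois = rois,
      tuft_ellipsoids = tufts,
      dropout_applied = attr(vg_post, "dropout_realized"),
      geometry = vg_post,
      seed = params$seed,
      params = params), class = "phantom_truth")
    list(stack = stack, truth = truth)
  })
}

# ---------------------------------------------------------------------------

gaussian_kernel <- function(sigma_vox, trunc = 3) {
  if (sigma_vox <= 1e-9) return(1)
  half <- max(1L, ceiling(trunc * sigma_vox))
  k <- exp(-0.5 * ((-half:half) / sigma_vox)^2)
  k / sum(k)
}

blur3 <- function(x, dims, sigma_z, sigma_y, sigma_x, trunc = 3) {
  v <- as.numeric(x)
  for (ax in 0:2) {
    s <- c(sigma_z, sigma_y, sigma_x)[ax + 1]
    k <- gaussian_kernel(s, trunc)
    if (length(k) > 1) v <- .conv_axis_3d(v, as.integer(dims), k, ax)
  }
  array(v, dim = dims)
}

#' Render a binary lumen mask through the confocal imaging model
#'
#' The green channel is the lumen mask times a multiplicative speckle field
#' (smooth lognormal-like texture at grain `speckle_grain`, standing in for
#' the granular appearance of sub-resolution microspheres), convolved with an
#' anisotropic Gaussian PSF, plus additive Gaussian sensor noise. The red
#' channel carries uniform parenchymal autofluorescence over
#' `background_mask`, likewise blurred and noisy. Intensities are clipped to
#' the dynamic range and rounded.
#'
#' @param true_mask Logical 3D array `(z, y, x)` of lumen voxels.
#' @param params A [phantom_params()] (degradation settings are read from it).
#' @param background_mask Logical array marking autofluorescent parenchyma;
#'   default: everything outside the lumina.
#' @param seed Integer seed.
#' @param geometry Optional [voxel_geometry()]; defaults to the one in
#'   `params`.
#' @return An [image_stack()] with channels `green` and `red`.
#' @export
render_imaging <- function(true_mask, params, background_mask = NULL,
                           seed = NULL, geometry = NULL) {
  dims <- dim(true_mask)
  if (!identical(as.integer(dims), as.integer(params$stack_shape)))
    stop("mask shape does not match params$stack_shape")
  if (is.null(geometry))
    geometry <- voxel_geometry(params$voxel_xy, params$voxel_xy, params$voxel_z)
  if (is.null(background_mask)) background_mask <- !true_mask
  maxv <- max_intensity(params$bit_depth)
  vi <- if (is.null(params$vessel_intensity)) 0.8 * maxv else params$vessel_intensity
  sx <- params$psf_sigma_xy / geometry$dx
  sy <- params$psf_sigma_xy / geometry$dy
  sz <- params$psf_sigma_z / geometry$dz
  with_seed(seed, {
    green <- vi * as.numeric(true_mask)
    if (params$speckle_contrast > 0 && params$speckle_grain > 0) {
      gx <- params$speckle_grain / geometry$dx
      gy <- params$speckle_grain / geometry$dy
      gz <- params$speckle_grain / geometry$dz
      field <- blur3(rnorm(prod(dims)), dims, gz, gy, gx, trunc = 2.5)
      field <- field / max(sd(field), 1e-12)
      green <- green * pmax(0, 1 + params$speckle_contrast * as.numeric(field))
    }
    green <- blur3(green, dims, sz, sy, sx)
    if (params$noise_sd > 0)
      green <- green + rnorm(prod(dims), 0, params$noise_sd)
    clipr <- function(x) array(.clip_round(as.numeric(x), maxv), dim = dims)
    channels <- list(green = clipr(green))
    if (isTRUE(params$render_red)) {
      red <- params$autofluorescence_level * as.numeric(background_mask)
      red <- blur3(red, dims, sz, sy, sx)
      if (params$noise_sd > 0)
        red <- red + rnorm(prod(dims), 0, params$noise_sd)
      channels$red <- clipr(red)
    }
    image_stack(channels, geometry,
                bit_depth = params$bit_depth,
                provenance = list(generator = "fmaquant phantom",
                                  kind = params$kind, seed = params$seed))
  })
}

# ---------------------------------------------------------------------------

#' Generate a synthetic immunostained 2D section
#'
#' Scatters brown DAB-like stained blobs over a pale counterstain background
#' until the stained pixel fraction is within 0.5 percentage points of the
#' target, and returns the exact realised fraction with the stain mask. A
#' synthetic stand-in for endothelial immunostain sections.
#'
#' @param area_fraction_target Target stained-area fraction in `[0, 1]`.
#' @param field_shape Image size `(height, width)` in pixels.
#' @param seed Integer seed.
#' @param noise_sd Per-channel Gaussian colour noise SD (0 = noiseless).
#' @param stain_rgb,background_rgb Mean RGB (0-255) of stain and counterstain.
#' @return A list: `image` (h x w x 3 array, 0-255), `truth_fraction`,
#'   `stain_mask` (logical h x w).
#' @export
generate_ihc_section <- function(area_fraction_target, field_shape = c(256, 256),
                                 seed = 1L, noise_sd = 0,
                                 stain_rgb = c(130, 80, 40),
                                 background_rgb = c(190, 180, 215)) {
  if (area_fraction_target < 0 || area_fraction_target > 1)
    stop("area_fraction_target must be in [0, 1]")
  h <- field_shape[1]; w <- field_shape[2]
  npix <- h * w
  with_seed(seed, {
    mask <- matrix(FALSE, h, w)
    frac <- 0
    attempts <- 0
    while (frac < area_fraction_target - 1e-12) {
      attempts <- attempts + 1
      if (attempts > 50000)
        stop("stained-area target ", area_fraction_target,
             " unreachable after 50000 blob attempts")
      ry <- runif(1, 2, 10); rx <- runif(1, 2, 10)
      repeat {
        cy <- runif(1, 1, h); cx <- runif(1, 1, w)
        y0 <- max(1, floor(cy - ry)); y1 <- min(h, ceiling(cy + ry))
        x0 <- max(1, floor(cx - rx)); x1 <- min(w, ceiling(cx + rx))
        yy <- y0:y1; xx <- x0:x1
        dy2 <- ((yy - cy) / ry)^2; dx2 <- ((xx - cx) / rx)^2
        blob <- outer(dy2, dx2, `+`) <= 1
        cand <- blob & !mask[yy, xx, drop = FALSE]
        gain <- sum(cand)
        if (frac + gain / npix <= area_fraction_target + 0.004 || (ry < 1.2 && rx < 1.2)) {
          sub <- mask[yy, xx, drop = FALSE]
          sub[cand] <- TRUE
          mask[yy, xx] <- sub
          frac <- frac + gain / npix
          break
        }
        ry <- ry * 0.7; rx <- rx * 0.7   # shrink and re-place
      }
    }
    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- matrix(background_rgb[ch], h, w)
      plane[mask] <- stain_rgb[ch]
      if (noise_sd > 0) plane <- plane + matrix(rnorm(npix, 0, noise_sd), h, w)
      img[, , ch] <- pmin(pmax(round(plane), 0), 255)
    }
    list(image = img, truth_fraction = sum(mask) / npix, stain_mask = mask)
  })
}
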