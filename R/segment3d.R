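#' Segment vascular lumina from an intensity stack
#'
#' Voxels strictly brighter than the threshold are lumen-positive. The
#' default threshold is Otsu's method computed over the whole stack (the
#' positivity rule is always explicit and recorded in provenance); a fixed
#' manual threshold is available as an escape hatch for stacks where Otsu is
#' unsuitable.
#'
#' @param stack An [image_stack()].
#' @param channel Channel name, default `"green"` (microsphere fluorescence).
#' @param method `"otsu"` or `"fixed"`.
#' @param manual_threshold Threshold intensity, required for
#'   `method = "fixed"`.
#' @return A `vessel_mask`: logical 3D array plus geometry and a provenance
#'   record including the threshold actually applied.
#' @export
segment_vessels <- function(stack, channel = "green",
                            method = c("otsu", "fixed"),
                            manual_threshold = NULL) {
  stopifnot(inherits(stack, "fma_stack"))
  method <- match.arg(method)
  if (!channel %in% names(stack$channels))
    stop("channel '", channel, "' not present; available: ",
         paste(names(stack$channels), collapse = ", "))
  vox <- stack$channels[[channel]]
  maxv <- max_intensity(stack$bit_depth)
  if (method == "otsu") {
    rng <- range(vox)
    if (diff(rng) == 0)
      stop("channel '", channel, "' is constant; Otsu thresholding is ",
           "undefined - use method = 'fixed' with a manual_threshold")
    img <- EBImage::Image(matrix(vox / maxv, nrow = dim(vox)[1]))
    thr <- EBImage::otsu(img, range = c(0, 1), levels = maxv + 1) * maxv
  } else {
    if (is.null(manual_threshold))
      stop("method = 'fixed' requires manual_threshold")
    if (manual_threshold < 0 || manual_threshold > maxv)
      stop("manual_threshold ", manual_threshold,
           " outside the stack dynamic range [0, ", maxv, "]")
    thr <- manual_threshold
  }
  mask <- vox > thr
  vessel_mask(mask, stack$geometry,
              provenance = list(list(step = "segment_vessels", channel = channel,
                                     method = method, threshold = thr)))
}

#' Construct a vessel mask
#'
#' @param mask Logical 3D array, `(z, y, x)` order.
#' @param geometry A [voxel_geometry()].
#' @param provenance List of processing-step records.
#' @return An object of class `vessel_mask`.
#' @export
vessel_mask <- function(mask, geometry, provenance = list()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3,
            inherits(geometry, "voxel_geometry"))
  structure(list(mask = mask, geometry = geometry, provenance = provenance),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("vessel mask: %d x %d x %d (z,y,x), %d positive voxels (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' 3D connected-component labelling
#'
#' @param vm A [vessel_mask()] (or logical 3D array).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A `labeled_components` object: integer label array (0 =
#'   background, labels 1..n contiguous), `n_components`, and per-component
#'   voxel counts.
#' @export
label_components <- function(vm, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  mask <- if (inherits(vm, "vessel_mask")) vm$mask else vm
  labs <- .cc_label_3d(as.logical(mask), as.integer(dim(mask)),
                       as.integer(connectivity))
  n <- attr(labs, "n")
  counts <- if (n > 0) tabulate(labs[labs > 0L], nbins = n) else integer(0)
  structure(list(labels = array(as.integer(labs), dim = dim(mask)),
                 n_components = n, component_sizes = counts,
                 connectivity = connectivity,
                 geometry = if (inherits(vm, "vessel_mask")) vm$geometry else NULL,
                 provenance = if (inherits(vm, "vessel_mask")) vm$provenance else list()),
            class = "labeled_components")
}

#' Remove small connected components
#'
#' Drops components below a voxel-count cutoff; isolated bright specks in FMA
#' stacks are typically microsphere clumps rather than perfused lumina. The
#' default cutoff (27 voxels, one 3x3x3 clump) is conservative and recorded
#' in provenance.
#'
#' @param lc A `labeled_components` from [label_components()].
#' @param min_voxels Components with fewer voxels are removed.
#' @return A [vessel_mask()] of the surviving components.
#' @export
filter_small_components <- function(lc, min_voxels = 27) {
  stopifnot(inherits(lc, "labeled_components"), min_voxels >= 0)
  keep <- which(lc$component_sizes >= min_voxels)
  mask <- array(lc$labels %in% keep & lc$labels > 0L, dim = dim(lc$labels))
  if (lc$n_components > 0 && length(keep) == 0)
    warning("min_voxels = ", min_voxels,
            " removed all ", lc$n_components, " components")
  geometry <- lc$geometry
  if (is.null(geometry))
    stop("labeled components carry no geometry; build them from a vessel_mask")
  prov <- c(lc$provenance,
            list(list(step = "filter_small_components", min_voxels = min_voxels,
                      removed = lc$n_components - length(keep),
                      kept = length(keep))))
  vessel_mask(mask, geometry, provenance = prov)
}

#' Exclude a region from a vessel mask
#'
#' The digital analogue of excluding the glomerular tuft with a negative pen
#' tool: output voxels are those positive in the mask and not in the ROI.
#'
#' @param vm A [vessel_mask()].
#' @param roi_mask Logical 3D array, same shape.
#' @return A [vessel_mask()]; provenance records the excluded voxel count.
#' @export
exclude_region <- function(vm, roi_mask) {
  stopifnot(inherits(vm, "vessel_mask"))
  if (!identical(dim(vm$mask), dim(roi_mask)))
    stop("roi_mask shape ", paste(dim(roi_mask), collapse = "x"),
         " does not match mask shape ", paste(dim(vm$mask), collapse = "x"))
  excluded <- sum(vm$mask & roi_mask)
  out <- vm$mask & !roi_mask
  vessel_mask(out, vm$geometry,
              provenance = c(vm$provenance,
                             list(list(step = "exclude_region",
                                       excluded_voxels = excluded))))
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b Logical arrays of identical shape.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Rasterise per-slice ROI polygons into a 3D mask
#'
#' Mirrors a drawn-ROI workflow: each polygon is given as
#' `list(z = <slice>, vertices = <n x 2 matrix of (x, y) pixel coordinates>)`
#' and is filled with the even-odd rule, evaluated at pixel centres
#' (half-open edges, so abutting polygons do not double-count pixels).
#'
#' @param polygons List of per-slice polygons as above; `z` is the 1-based
#'   slice index, vertex coordinates are 0-based pixel positions.
#' @param dims Stack dimensions `(z, y, x)`.
#' @return Logical 3D array.
#' @export
roi_from_polygons <- function(polygons, dims) {
  mask <- array(FALSE, dim = dims)
  for (p in polygons) {
    z <- p$z
    if (is.null(z) || z < 1 || z > dims[1])
      stop("polygon slice index z out of range: ", z)
    v <- p$vertices
    if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
    v <- as.matrix(v)
    if (nrow(v) < 3) stop("polygon needs at least 3 vertices")
    xs <- v[, 1]; ys <- v[, 2]
    x0 <- max(1L, floor(min(xs))); x1 <- min(dims[3], ceiling(max(xs)) + 1L)
    y0 <- max(1L, floor(min(ys))); y1 <- min(dims[2], ceiling(max(ys)) + 1L)
    if (x1 < x0 || y1 < y0) next
    px <- (x0:x1) - 0.5          # pixel centres, 0-based coordinates
    py <- (y0:y1) - 0.5
    grid_x <- matrix(px, length(py), length(px), byrow = TRUE)
    grid_y <- matrix(py, length(py), length(px))
    inside <- matrix(FALSE, length(py), length(px))
    n <- nrow(v)
    j <- n
    for (i in seq_len(n)) {
      yi <- ys[i]; yj <- ys[j]; xi <- xs[i]; xj <- xs[j]
      crosses <- (yi > grid_y) != (yj > grid_y)
      if (any(crosses)) {
        xint <- (xj - xi) * (grid_y - yi) / (yj - yi) + xi
        inside <- xor(inside, crosses & (grid_x < xint))
      }
      j <- i
    }
    sub <- mask[z, y0:y1, x0:x1]
    mask[z, y0:y1, x0:x1] <- sub | inside
  }
  mask
}

#' Read ROI masks from a JSON polygon file or a binary TIFF
#'
#' JSON files hold a list of per-slice polygons
#' (`{"z": 4, "vertices": [[x, y], ...]}`), rasterised with
#' [roi_from_polygons()]; TIFF files are read as binary multi-page masks
#' (any positive pixel is inside).
#'
#' @param path `.json` polygon file or `.tif`/`.tiff` binary mask.
#' @param dims Stack dimensions `(z, y, x)` (required for polygons; checked
#'   against TIFF masks).
#' @return Logical 3D array.
#' @export
read_roi_mask <- function(path, dims) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    polys <- jsonlite::read_json(path, simplifyVector = FALSE)
    polys <- lapply(polys, function(p)
      list(z = p$z, vertices = do.call(rbind, lapply(p$vertices, unlist))))
    roi_from_polygons(polys, dims)
  } else {
    vox <- read_channel_tiff(path, 8L)
    if (!identical(as.integer(dim(vox)), as.integer(dims)))
      stop("ROI mask shape ", paste(dim(vox), collapse = "x"),
           " does not match stack dims ", paste(dims, collapse = "x"))
    array(vox > 0, dim = dims)
  }
}
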