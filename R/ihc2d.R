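#' Stain-positive mask by colour deconvolution
#'
#' Separates a brightfield RGB section into haematoxylin and DAB optical
#' density channels using the standard published stain vectors (Ruifrok &
#' Johnston) and thresholds the DAB channel. The threshold is recorded in the
#' result's attributes. A `"fixed"` method thresholds the DAB optical density
#' at a user value; `"hue"` gates on brownish hue as a fallback for
#' non-standard chromogens.
#'
#' @param image RGB array `(h, w, 3)`, intensities 0-255.
#' @param method `"deconv"` (default), `"fixed"` or `"hue"`.
#' @param dab_threshold Threshold on the DAB concentration (deconv/fixed
#'   modes), default 0.15.
#' @return Logical `(h, w)` matrix of stain-positive pixels, with attributes
#'   `method` and `threshold`.
#' @export
stain_mask <- function(image, method = c("deconv", "fixed", "hue"),
                       dab_threshold = 0.15) {
  method <- match.arg(method)
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("stain_mask requires an RGB image (h x w x 3); got a ",
         length(dim(image)), "-dimensional array")
  h <- dim(image)[1]; w <- dim(image)[2]
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  if (method == "hue") {
    # brown: red clearly above blue, moderate darkness
    m <- (r > b + 20) & (r > g) & (r + g + b < 600)
    attr(m, "method") <- "hue"; attr(m, "threshold") <- NA_real_
    return(m)
  }
  od <- function(x) -log10(pmax(x, 1) / 255)
  odr <- od(r); odg <- od(g); odb <- od(b)
  # Ruifrok-Johnston stain vectors: haematoxylin, DAB, residual (unit norm)
  he <- c(0.650, 0.704, 0.286)
  dab <- c(0.268, 0.570, 0.776)
  res <- c(he[2] * dab[3] - he[3] * dab[2],
           he[3] * dab[1] - he[1] * dab[3],
           he[1] * dab[2] - he[2] * dab[1])
  res <- res / sqrt(sum(res^2))
  M <- rbind(he / sqrt(sum(he^2)), dab / sqrt(sum(dab^2)), res)
  Minv <- solve(t(M))   # concentrations = Minv %*% optical densities
  conc_dab <- Minv[2, 1] * odr + Minv[2, 2] * odg + Minv[2, 3] * odb
  m <- matrix(conc_dab > dab_threshold, h, w)
  attr(m, "method") <- method
  attr(m, "threshold") <- dab_threshold
  m
}

#' Proportional stained area within a region of interest
#'
#' @param mask Logical stain mask (`h x w`).
#' @param roi Logical ROI (`h x w`), non-empty.
#' @return Fraction of ROI pixels that are stain-positive, in `[0, 1]`.
#' @export
proportional_area <- function(mask, roi) {
  if (!identical(dim(mask), dim(roi)))
    stop("mask and ROI shapes differ")
  n <- sum(roi)
  if (n == 0) stop("empty ROI")
  sum(mask & roi) / n
}

#' Proportional immunostained area over glomerular profiles or cortical fields
#'
#' The conventional 2D capillary-density comparator: stained-area fraction in
#' each ROI, with the arithmetic mean across ROIs. In tubulointerstitial mode
#' any supplied glomerular ROIs are excluded from each field before the
#' fraction is computed (mirroring area measurement "excluding glomeruli").
#' The study design this emulates used 30 glomerular profiles and 10 cortical
#' fields per section.
#'
#' @param image RGB array `(h, w, 3)`.
#' @param roi_list List of logical `(h, w)` ROIs (>= 1).
#' @param compartment `"glomerular"` or `"tubulointerstitial"`.
#' @param glomerular_rois Optional list of logical masks excluded from fields
#'   in tubulointerstitial mode.
#' @param method,dab_threshold Passed to [stain_mask()].
#' @return A `stain_metrics` object with `per_profile_fractions`,
#'   `mean_fraction`, `n_profiles` and `compartment`.
#' @export
evaluate_section <- function(image, roi_list,
                             compartment = c("glomerular", "tubulointerstitial"),
                             glomerular_rois = NULL,
                             method = "deconv", dab_threshold = 0.15) {
  compartment <- match.arg(compartment)
  if (length(roi_list) < 1) stop("at least one ROI is required")
  m <- stain_mask(image, method = method, dab_threshold = dab_threshold)
  excl <- NULL
  if (compartment == "tubulointerstitial" && length(glomerular_rois) > 0)
    excl <- Reduce(`|`, glomerular_rois)
  fr <- vapply(roi_list, function(roi) {
    if (!is.null(excl)) roi <- roi & !excl
    proportional_area(m, roi)
  }, numeric(1))
  structure(list(per_profile_fractions = fr, mean_fraction = mean(fr),
                 n_profiles = length(fr), compartment = compartment,
                 threshold = attr(m, "threshold"), method = attr(m, "method")),
            class = "stain_metrics")
}

#' @export
print.stain_metrics <- function(x, ...) {
  cat(sprintf("%s immunostain: mean proportional area %.4f over %d profiles\n",
              x$compartment, x$mean_fraction, x$n_profiles))
  invisible(x)
}

#' Seeded random rectangular fields within an image
#'
#' Mirrors "randomly selected cortical fields" reproducibly: uniform
#' placement with rejection of out-of-bounds fields.
#'
#' @param image_shape `(h, w)` of the section.
#' @param n Number of fields.
#' @param field_size `(h, w)` of each field.
#' @param seed Integer seed.
#' @return List of logical `(h, w)` masks.
#' @export
random_fields <- function(image_shape, n, field_size, seed = NULL) {
  h <- image_shape[1]; w <- image_shape[2]
  fh <- field_size[1]; fw <- field_size[2]
  if (fh > h || fw > w) stop("field larger than the image")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      y0 <- sample.int(h - fh + 1L, 1)
      x0 <- sample.int(w - fw + 1L, 1)
      m <- matrix(FALSE, h, w)
      m[y0:(y0 + fh - 1L), x0:(x0 + fw - 1L)] <- TRUE
      m
    })
  })
}

#' Write an RGB section image to PNG
#'
#' @param image RGB array `(h, w, 3)`, 0-255.
#' @param path Output path.
#' @export
write_section <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read an RGB section image from PNG
#'
#' @param path PNG path.
#' @return RGB array `(h, w, 3)`, 0-255.
#' @export
read_section <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) stop("grayscale image; an RGB section is required")
  round(img[, , 1:3] * 255)
}
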