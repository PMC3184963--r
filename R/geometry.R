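#' Voxel geometry of a confocal stack
#'
#' Records the physical size of a voxel. The axial step defaults to the
#' 0.8141 um optical-section spacing used throughout the package; the lateral
#' pitch has no universal default at acquisition time and must always be
#' stated explicitly by the data source (generators default to 0.73 um/pixel,
#' typical for a 20x objective at zoom 2, and record it in metadata).
#'
#' @param dx,dy Lateral pixel pitch, um/pixel.
#' @param dz Axial step between optical sections, um (default 0.8141).
#' @return An object of class `voxel_geometry` with fields `dx`, `dy`, `dz`
#'   and the derived `voxel_volume` in um^3.
#' @export
voxel_geometry <- function(dx, dy = dx, dz = 0.8141) {
  vals <- c(dx = dx, dy = dy, dz = dz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("voxel geometry components must be strictly positive: ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "))
  structure(list(dx = dx, dy = dy, dz = dz, voxel_volume = dx * dy * dz),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel geometry: dx=%g dy=%g dz=%g um (voxel volume %g um^3)\n",
              x$dx, x$dy, x$dz, x$voxel_volume))
  invisible(x)
}

# pitch vector in (z, y, x) order, matching array dims
geom_pitch <- function(geometry) c(geometry$dz, geometry$dy, geometry$dx)

#' Ellipsoid with semi-axes in micrometres
#'
#' Semi-axes are stored sorted `a >= b >= c`. `rotation` is a 3x3 matrix whose
#' rows are the principal axis directions expressed in stack `(z, y, x)`
#' coordinates (row i corresponds to semi-axis i).
#'
#' @param a,b,c Semi-axis lengths in um.
#' @param center Centre in um, `(z, y, x)`.
#' @param rotation 3x3 rotation matrix (rows = principal axes in stack frame).
#' @return An object of class `fma_ellipsoid`.
#' @export
ellipsoid <- function(a, b, c, center = c(0, 0, 0), rotation = diag(3)) {
  semi <- c(a, b, c)
  if (any(!is.finite(semi)) || any(semi <= 0))
    stop("ellipsoid semi-axes must be strictly positive")
  ord <- order(semi, decreasing = TRUE)
  structure(list(a = semi[ord][1], b = semi[ord][2], c = semi[ord][3],
                 center = center, rotation = rotation[ord, , drop = FALSE]),
            class = "fma_ellipsoid")
}

#' Ellipsoid volume, V = 4*pi*a*b*c/3
#'
#' @param e An [ellipsoid()].
#' @return Volume in um^3.
#' @export
ellipsoid_volume <- function(e) {
  stopifnot(inherits(e, "fma_ellipsoid"))
  4 * pi * e$a * e$b * e$c / 3
}

#' @export
print.fma_ellipsoid <- function(x, ...) {
  cat(sprintf("ellipsoid: a=%.2f b=%.2f c=%.2f um, V=%.4g um^3\n",
              x$a, x$b, x$c, ellipsoid_volume(x)))
  invisible(x)
}

# Rotation about the stack z axis by `theta` radians, expressed in the
# (z, y, x) row convention used throughout.
rotation_about_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  # rows: principal axes in (z,y,x); axes 1 and 2 rotate in the (y,x) plane,
  # axis 3 stays along stack z
  rbind(c(0, st, ct),
        c(0, ct, -st),
        c(1, 0, 0))
}

# Uniform random 3x3 rotation (rows orthonormal), used for phantom orientation.
random_rotation <- function() {
  repeat {
    m <- matrix(rnorm(9), 3, 3)
    q <- qr(m)
    r <- qr.Q(q)
    d <- sign(diag(qr.R(q)))
    r <- r * rep(d, each = 3)
    if (det(r) < 0) r[3, ] <- -r[3, ]
    if (abs(det(r) - 1) < 1e-8) return(t(r))
  }
}

# Rasterise a solid ellipsoid into a logical (nz, ny, nx) array.
ellipsoid_mask <- function(e, dims, geometry) {
  m <- .ellipsoid_mask_cpp(as.integer(dims), geom_pitch(geometry),
                           as.numeric(e$center), e$rotation,
                           c(e$a, e$b, e$c))
  array(m, dim = dims)
}
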