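#' Construct an image stack
#'
#' An image stack bundles one or two intensity channels (3D arrays in
#' `(z, y, x)` axis order), the voxel geometry, the bit depth and a
#' provenance record. Channel names follow the two-colour FMA convention:
#' `green` carries microsphere fluorescence delineating perfused lumina,
#' `red` carries tubular autofluorescence.
#'
#' @param channels Named list of 3D numeric arrays, identical dims, values in
#'   `[0, 2^bit_depth - 1]`.
#' @param geometry A [voxel_geometry()].
#' @param bit_depth 8 or 16.
#' @param provenance Optional list describing how the stack was produced.
#' @return An object of class `fma_stack`.
#' @export
image_stack <- function(channels, geometry, bit_depth = 8, provenance = list()) {
  stopifnot(inherits(geometry, "voxel_geometry"), bit_depth %in% c(8L, 16L))
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a named list of 3D arrays")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3D array in (z, y, x) order")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share the same dimensions")
  for (nm in names(channels)) {
    if (any(channels[[nm]] < 0)) stop("channel '", nm, "' has negative intensities")
  }
  structure(list(channels = channels, geometry = geometry,
                 bit_depth = as.integer(bit_depth), provenance = provenance),
            class = "fma_stack")
}

#' @export
print.fma_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("FMA image stack: %d x %d x %d (z,y,x), channels: %s, %d-bit\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", "),
              x$bit_depth))
  print(x$geometry)
  invisible(x)
}

stack_dims <- function(stack) dim(stack$channels[[1]])

max_intensity <- function(bit_depth) 2^bit_depth - 1

sidecar_path <- function(path) sub("\\.tiff?$", "", path, ignore.case = TRUE) |>
  paste0(".json")

channel_path <- function(path, channel) {
  base <- sub("\\.tiff?$", "", path, ignore.case = TRUE)
  ext <- if (grepl("\\.tiff$", path, ignore.case = TRUE)) ".tiff" else ".tif"
  paste0(base, "_", channel, ext)
}

#' Write an image stack to multi-page TIFF with a JSON geometry sidecar
#'
#' Each channel is written to its own multi-page grayscale TIFF
#' (`<base>_<channel>.tif`, page order = z). Voxel geometry, channel names,
#' bit depth and provenance go to a JSON sidecar (`<base>.json`), which is the
#' authoritative geometry record on re-read. Round-trips are bit-exact.
#'
#' @param stack An [image_stack()].
#' @param path Base output path, e.g. `"stack.tif"`.
#' @return Invisibly, the list of files written.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fma_stack"))
  maxv <- max_intensity(stack$bit_depth)
  files <- character(0)
  for (nm in names(stack$channels)) {
    vox <- stack$channels[[nm]]
    pages <- lapply(seq_len(dim(vox)[1]), function(z) vox[z, , ] / maxv)
    fp <- channel_path(path, nm)
    ok <- tiff::writeTIFF(pages, fp, bits.per.sample = stack$bit_depth)
    if (!isTRUE(ok) && !identical(ok, length(pages)))
      stop("failed to write TIFF: ", fp)
    files <- c(files, fp)
  }
  meta <- list(dx = stack$geometry$dx, dy = stack$geometry$dy,
               dz = stack$geometry$dz, units = "um",
               channels = as.list(names(stack$channels)),
               bit_depth = stack$bit_depth,
               provenance = stack$provenance)
  sp <- sidecar_path(path)
  jsonlite::write_json(meta, sp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, sp))
}

read_channel_tiff <- function(fp, bit_depth) {
  pages <- tiff::readTIFF(fp, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L)
    stop("inconsistent page shapes in ", fp)
  d2 <- shapes[[1]]
  vox <- array(0, dim = c(length(pages), d2[1], d2[2]))
  maxv <- max_intensity(bit_depth)
  for (z in seq_along(pages)) vox[z, , ] <- round(pages[[z]] * maxv)
  vox
}

#' Read an image stack written by [write_stack()]
#'
#' Geometry resolution order: JSON sidecar first, then the
#' `geometry_override` argument. A stack with neither is refused — the
#' pipeline never assumes a pixel size silently.
#'
#' @param path Base path given to [write_stack()].
#' @param geometry_override Optional [voxel_geometry()] used when no sidecar
#'   is present (or to override it, with a warning on conflict).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, geometry_override = NULL) {
  sp <- sidecar_path(path)
  meta <- NULL
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(meta) && is.null(geometry_override))
    stop("no geometry available for ", path,
         ": missing sidecar fields dx, dy, dz and no geometry_override given")
  if (!is.null(meta)) {
    geometry <- voxel_geometry(meta$dx, meta$dy, meta$dz)
    if (!is.null(geometry_override)) {
      if (abs(geometry$dz - geometry_override$dz) > 1e-12 ||
          abs(geometry$dx - geometry_override$dx) > 1e-12 ||
          abs(geometry$dy - geometry_override$dy) > 1e-12)
        warning("geometry override conflicts with sidecar; sidecar wins")
    }
    bit_depth <- if (!is.null(meta$bit_depth)) meta$bit_depth else 8L
    chans <- unlist(meta$channels)
  } else {
    geometry <- geometry_override
    bit_depth <- 8L
    # probe for channel files
    chans <- c("green", "red")
    chans <- chans[file.exists(vapply(chans, function(ch) channel_path(path, ch), ""))]
    if (length(chans) == 0 && file.exists(path)) chans <- NA  # single bare file
  }
  channels <- list()
  if (length(chans) == 1 && is.na(chans[1])) {
    channels[["green"]] <- read_channel_tiff(path, bit_depth)
  } else {
    for (nm in chans) channels[[nm]] <- read_channel_tiff(channel_path(path, nm), bit_depth)
  }
  prov <- if (!is.null(meta)) meta$provenance else list()
  prov$source <- path
  prov$geometry_source <- if (!is.null(meta)) "sidecar" else "override"
  image_stack(channels, geometry, bit_depth = bit_depth, provenance = prov)
}
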