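# S3 containers shared by all pipeline stages.
#
# Conventions used throughout the package:
#   * matrices are indexed [row, col]; row = y, col = x
#   * pixel coordinates are 0-based with pixel centres at integer positions
#   * physical position (um) = pixel coordinate * pixel size for that axis
#   * straightened geometry: row 0 = proximal (dorsal) end, the shaft sits on
#     the exact centre column

#' Planar fluorescence image
#'
#' A single-channel 2D image with physical pixel sizes, e.g. a maximum
#' intensity projection of a confocal stack.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixel_size_x,pixel_size_y Physical pixel size in micrometres per
#'   pixel along x (columns) and y (rows).
#' @return An object of class `axo_image`.
#' @export
planar_image <- function(pixels, pixel_size_x, pixel_size_y) {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("image intensities must be finite and non-negative")
  check_pixel_sizes(pixel_size_x, pixel_size_y)
  structure(
    list(pixels = pixels,
         pixel_size_x = as.numeric(pixel_size_x),
         pixel_size_y = as.numeric(pixel_size_y)),
    class = "axo_image")
}

#' Three-dimensional image stack
#'
#' @param voxels Numeric 3D array with dimensions (y, x, z).
#' @param pixel_size_x,pixel_size_y In-plane pixel sizes (um/pixel).
#' @param z_step Axial step between slices (um).
#' @return An object of class `axo_stack`.
#' @export
image_stack <- function(voxels, pixel_size_x, pixel_size_y, z_step) {
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(is.numeric(voxels), length(dim(voxels)) == 3L, all(dim(voxels) >= 1))
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("stack intensities must be finite and non-negative")
  check_pixel_sizes(pixel_size_x, pixel_size_y)
  if (!is.numeric(z_step) || length(z_step) != 1L || !is.finite(z_step) || z_step <= 0)
    stop("z_step must be a single positive number")
  structure(
    list(voxels = voxels,
         pixel_size_x = as.numeric(pixel_size_x),
         pixel_size_y = as.numeric(pixel_size_y),
         z_step = as.numeric(z_step)),
    class = "axo_stack")
}

#' Manually traced axon path
#'
#' An ordered polyline in physical micrometre coordinates. The first vertex is
#' the proximal (dorsal) end of the axon. Vertices are 2D (x, y) or,
#' uniformly, 3D (x, y, z).
#'
#' @param vertices Numeric matrix with 2 or 3 columns (x, y[, z]) in um.
#' @return An object of class `axo_trace`.
#' @export
axon_trace <- function(vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) < 2L || ncol(vertices) > 3L)
    stop("trace vertices must have 2 or 3 columns (x, y[, z])")
  if (nrow(vertices) < 2L)
    stop("a trace needs at least 2 vertices")
  if (!all(is.finite(vertices)))
    stop("trace coordinates must be finite")
  d <- diff(vertices)
  if (any(rowSums(d * d) == 0))
    stop("consecutive trace vertices must be distinct")
  colnames(vertices) <- c("x", "y", "z")[seq_len(ncol(vertices))]
  structure(list(vertices = vertices), class = "axo_trace")
}

#' @export
print.axo_image <- function(x, ...) {
  cat(sprintf("<axo_image> %d x %d px (%.4f x %.4f um/px)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_y, x$pixel_size_x))
  invisible(x)
}

#' @export
print.axo_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<axo_stack> %d x %d px, %d slices (%.4f x %.4f um/px, dz %.3f um)\n",
              d[1], d[2], d[3], x$pixel_size_y, x$pixel_size_x, x$z_step))
  invisible(x)
}

#' @export
print.axo_trace <- function(x, ...) {
  cat(sprintf("<axo_trace> %d vertices (%dD), length %.2f um\n",
              nrow(x$vertices), ncol(x$vertices), trace_length(x)))
  invisible(x)
}

#' @export
print.axo_straightened <- function(x, ...) {
  cat(sprintf(paste0("<axo_straightened> %d rows x %d cols, width %.1f um, ",
                     "axon length %.2f um\n"),
              nrow(x$pixels), ncol(x$pixels), x$width_um, x$axon_length_um))
  invisible(x)
}

#' @export
print.axo_mask <- function(x, ...) {
  cat(sprintf(paste0("<axo_mask> %d rows x %d cols, %d foreground px, ",
                     "min collateral %.2f um\n"),
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$min_collateral_um))
  invisible(x)
}

check_pixel_sizes <- function(pixel_size_x, pixel_size_y) {
  for (p in list(pixel_size_x, pixel_size_y)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
      stop("pixel sizes must be single positive numbers (um/pixel)")
  }
  invisible(TRUE)
}

# Straightened band image (internal constructor; produced by straighten_image).
# `valid` flags pixels whose source sample fell inside the original image.
new_straightened <- function(pixels, valid, pixel_size_x, pixel_size_y,
                             width_um, axon_length_um) {
  structure(
    list(pixels = pixels, valid = valid,
         pixel_size_x = pixel_size_x, pixel_size_y = pixel_size_y,
         width_um = width_um, axon_length_um = axon_length_um),
    class = c("axo_straightened", "axo_image"))
}

# Binary collateral mask in straightened geometry (internal constructor).
new_mask <- function(pixels, valid, pixel_size_x, pixel_size_y,
                     width_um, axon_length_um, min_collateral_um) {
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, valid = valid,
         pixel_size_x = pixel_size_x, pixel_size_y = pixel_size_y,
         width_um = width_um, axon_length_um = axon_length_um,
         min_collateral_um = min_collateral_um),
    class = c("axo_mask", "axo_image"))
}

# centre column index (1-based) of a straightened-geometry image
centre_column <- function(x) (ncol(x$pixels) + 1L) %/% 2L

is_str_geometry <- function(x) {
  inherits(x, "axo_straightened") || inherits(x, "axo_mask")
}
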