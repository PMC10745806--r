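# On-disk artifacts: TIFF stacks/images, axon traces (ImageJ .roi or CSV),
# and tab-separated profile arrays.
#
# Pixel-size metadata: baseline TIFF resolution tags are honoured on read
# (interpreted as pixels per micrometre when no resolution unit is recorded,
# the ImageJ convention; inch/cm units are converted). Because the TIFF writer
# used here cannot emit resolution tags, every written image carries a JSON
# sidecar `<path>.json` with pixel sizes and the intensity scale. Resolution
# precedence on read: explicit arguments > sidecar > TIFF tags > error.

#' Read a single-channel TIFF stack
#'
#' @param path Path to a single-channel TIFF file (one or more slices).
#' @param pixel_size_x,pixel_size_y Optional overrides for the in-plane pixel
#'   sizes (um/pixel). An override always wins over file metadata; if neither
#'   an override nor metadata is available the call fails.
#' @param z_step Optional override for the axial step (um); defaults to the
#'   sidecar value or 1 um for single-slice stacks when absent.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_x = NULL, pixel_size_y = NULL,
                       z_step = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  slices <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  if (length(dim(slices[[1]])) > 2L)
    stop("multi-channel TIFF given without a channel selector; ",
         "supply a single-channel image")
  meta <- read_sidecar(path)
  scale <- resolve_scale(meta, attributes(slices[[1]]))
  res <- resolve_pixel_sizes(pixel_size_x, pixel_size_y, meta,
                             attributes(slices[[1]]), path)
  if (is.null(z_step)) z_step <- meta$z_step
  if (is.null(z_step)) {
    if (length(slices) > 1L)
      stop("z_step unknown for multi-slice stack ", path,
           ": supply z_step or a sidecar")
    z_step <- 1
  }
  vox <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]] * scale
  image_stack(vox, res$x, res$y, z_step)
}

#' Write an image stack as TIFF (with JSON metadata sidecar)
#'
#' Integer data round-trips exactly at the requested bit depth; arbitrary
#' float data is stored as 32-bit float scaled to its maximum, recorded in the
#' sidecar, giving better than 1e-6 relative fidelity.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; a sidecar `<path>.json` is written alongside.
#' @param bits Bits per sample: 8 or 16 (integer data) or 32 (float).
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "axo_stack"))
  nz <- dim(stack$voxels)[3]
  slices <- lapply(seq_len(nz), function(k) stack$voxels[, , k])
  scale <- write_tiff_slices(slices, path, bits)
  write_sidecar(path, list(pixel_size_x = stack$pixel_size_x,
                           pixel_size_y = stack$pixel_size_y,
                           z_step = stack$z_step, scale = scale, bits = bits))
  invisible(path)
}

#' Read a planar image (single TIFF page)
#'
#' @inheritParams read_stack
#' @return An [planar_image()]. A straightened image or mask written by this
#'   package is restored with its validity mask and geometry fields.
#' @export
read_image <- function(path, pixel_size_x = NULL, pixel_size_y = NULL) {
  st <- read_stack(path, pixel_size_x, pixel_size_y, z_step = 1)
  if (dim(st$voxels)[3] != 1L) stop(path, " has multiple slices; use read_stack")
  img <- planar_image(st$voxels[, , 1], st$pixel_size_x, st$pixel_size_y)
  meta <- read_sidecar(path)
  if (!is.null(meta$kind) && meta$kind %in% c("straightened", "mask")) {
    valid <- matrix(TRUE, nrow(img$pixels), ncol(img$pixels))
    if (!is.null(meta$invalid_idx) && length(meta$invalid_idx))
      valid[unlist(meta$invalid_idx)] <- FALSE
    if (meta$kind == "straightened") {
      img <- new_straightened(img$pixels, valid, img$pixel_size_x,
                              img$pixel_size_y, meta$width_um,
                              meta$axon_length_um)
    } else {
      img <- new_mask(ifelse(img$pixels > 0, 1L, 0L), valid, img$pixel_size_x,
                      img$pixel_size_y, meta$width_um, meta$axon_length_um,
                      meta$min_collateral_um)
    }
  }
  img
}

#' Write a planar image, straightened image, or mask as TIFF
#'
#' Masks are written as 0/255 8-bit images; straightened images keep their
#' validity mask and geometry in the sidecar.
#'
#' @param image An `axo_image`, `axo_straightened`, or `axo_mask`.
#' @param path Output TIFF path.
#' @param bits Bits per sample (ignored for masks, which are 8-bit).
#' @export
write_image <- function(image, path, bits = 16L) {
  meta <- list(pixel_size_x = image$pixel_size_x,
               pixel_size_y = image$pixel_size_y)
  if (inherits(image, "axo_mask")) {
    scale <- write_tiff_slices(list(image$pixels * 255), path, 8L)
    meta <- c(meta, list(kind = "mask", scale = scale, bits = 8L,
                         width_um = image$width_um,
                         axon_length_um = image$axon_length_um,
                         min_collateral_um = image$min_collateral_um,
                         invalid_idx = which(!image$valid)))
  } else if (inherits(image, "axo_straightened")) {
    scale <- write_tiff_slices(list(image$pixels), path, bits)
    meta <- c(meta, list(kind = "straightened", scale = scale, bits = bits,
                         width_um = image$width_um,
                         axon_length_um = image$axon_length_um,
                         invalid_idx = which(!image$valid)))
  } else {
    scale <- write_tiff_slices(list(image$pixels), path, bits)
    meta <- c(meta, list(scale = scale, bits = bits))
  }
  write_sidecar(path, meta)
  invisible(path)
}

#' Maximum intensity projection of a stack
#'
#' Collapses the z dimension by taking, for every (y, x) position, the maximum
#' intensity over all slices; pixel sizes are carried over.
#'
#' @param stack An [image_stack()].
#' @return A [planar_image()].
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "axo_stack"))
  mip <- apply(stack$voxels, c(1, 2), max)
  planar_image(mip, stack$pixel_size_x, stack$pixel_size_y)
}

#' Read an axon trace from an ImageJ .roi file or a CSV point list
#'
#' ImageJ .roi files must be of the polyline (segmented line) type. CSV files
#' hold columns x,y[,z] (header optional); `units` states whether CSV
#' coordinates are pixels or micrometres. Coordinates are returned in
#' micrometres, ordering preserved, first vertex = proximal end.
#'
#' @param path Path to a `.roi` or `.csv`/`.txt` file.
#' @param pixel_size_x,pixel_size_y Pixel sizes (um/pixel) used to convert
#'   pixel coordinates to micrometres.
#' @param units For CSV input: `"px"` (default, ImageJ-style point lists) or
#'   `"um"`. `.roi` coordinates are always pixels.
#' @param z_step Axial step (um) used to convert a pixel-unit z column.
#' @return An [axon_trace()].
#' @export
read_trace <- function(path, pixel_size_x, pixel_size_y,
                       units = c("px", "um"), z_step = 1) {
  units <- match.arg(units)
  if (grepl("\\.roi$", path, ignore.case = TRUE)) {
    pts <- read_roi_polyline(path)
    return(axon_trace(cbind(x = pts[, 1] * pixel_size_x,
                            y = pts[, 2] * pixel_size_y)))
  }
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE]+\\s*[,\t ]", first)
  tab <- utils::read.csv(path, header = has_header)
  if (ncol(tab) < 2L || ncol(tab) > 3L)
    stop("trace CSV must have 2 or 3 numeric columns (x,y[,z])")
  m <- as.matrix(tab)
  if (!is.numeric(m) || !all(is.finite(m))) stop("non-numeric trace CSV")
  if (units == "px") {
    m[, 1] <- m[, 1] * pixel_size_x
    m[, 2] <- m[, 2] * pixel_size_y
    if (ncol(m) == 3L) m[, 3] <- m[, 3] * z_step
  }
  colnames(m) <- c("x", "y", "z")[seq_len(ncol(m))]
  axon_trace(m)
}

#' Write an axon trace
#'
#' CSV output holds micrometre (or pixel) coordinates with a header; `.roi`
#' output is an ImageJ-compatible polyline with sub-pixel resolution.
#'
#' @param trace An [axon_trace()].
#' @param path Output path; format chosen by extension (`.roi` vs CSV).
#' @param pixel_size_x,pixel_size_y Pixel sizes used to convert micrometres to
#'   pixel coordinates for `.roi` or pixel-unit CSV output.
#' @param units CSV coordinate units to write (`"um"` default).
#' @export
write_trace <- function(trace, path, pixel_size_x = NULL, pixel_size_y = NULL,
                        units = c("um", "px")) {
  stopifnot(inherits(trace, "axo_trace"))
  units <- match.arg(units)
  v <- trace$vertices
  if (grepl("\\.roi$", path, ignore.case = TRUE)) {
    if (is.null(pixel_size_x) || is.null(pixel_size_y))
      stop("pixel sizes are required to write .roi (pixel) coordinates")
    if (ncol(v) == 3L) stop("ImageJ .roi polylines are 2D; project first")
    write_roi_polyline(cbind(v[, "x"] / pixel_size_x,
                             v[, "y"] / pixel_size_y), path)
    return(invisible(path))
  }
  if (units == "px") {
    if (is.null(pixel_size_x) || is.null(pixel_size_y))
      stop("pixel sizes are required to write pixel-unit CSV")
    v[, "x"] <- v[, "x"] / pixel_size_x
    v[, "y"] <- v[, "y"] / pixel_size_y
  }
  utils::write.csv(as.data.frame(v), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write profiles as a tab-separated array
#'
#' One header row with the position of every column in micrometres, then one
#' row of mean values per image.
#'
#' @param profile An `axo_profile` (per-image rows are written), or a list of
#'   equal-length numeric vectors sharing one `positions` attribute.
#' @param path Output TSV path.
#' @param positions Positions (um) when `profile` is a plain list.
#' @export
write_profiles_tsv <- function(profile, path, positions = NULL) {
  if (inherits(profile, "axo_profile")) {
    m <- profile$per_image
    positions <- profile$positions
  } else {
    lens <- lengths(profile)
    if (length(unique(lens)) != 1L)
      stop("profiles in one file must share length")
    m <- do.call(rbind, profile)
    if (is.null(positions)) stop("positions required for plain profile lists")
  }
  if (length(positions) != ncol(m))
    stop("positions length must match profile length")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sprintf("%.10g", positions), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.10g", m[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' Read a tab-separated profile array
#'
#' @param path TSV written by [write_profiles_tsv()].
#' @return List with `positions` (um) and `values` (matrix, one row per image).
#' @export
read_profiles_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("profile TSV needs a header and >= 1 row")
  positions <- as.numeric(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  values <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  if (any(is.na(positions)) || any(is.na(values))) stop("non-numeric TSV")
  if (ncol(values) != length(positions))
    stop("row length does not match header")
  list(positions = positions, values = values)
}

# ---- internal helpers -------------------------------------------------------

write_tiff_slices <- function(slices, path, bits) {
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")
  mx <- max(vapply(slices, max, numeric(1)), 0)
  if (bits < 32L) {
    full <- 2^bits - 1
    intish <- all(vapply(slices, function(s)
      all(abs(s - round(s)) < 1e-9), logical(1)))
    if (!intish || mx > full)
      stop("integer TIFF output needs integer intensities within 0..", full,
           "; use bits = 32 for float data")
    scale <- full
  } else {
    scale <- if (mx > 0) mx else 1
  }
  tiff::writeTIFF(lapply(slices, function(s) s / scale), path,
                  bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  scale
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
}

resolve_scale <- function(meta, info) {
  if (!is.null(meta$scale)) return(meta$scale)
  bits <- info$bits.per.sample
  if (!is.null(bits) && bits < 32) 2^bits - 1 else 1
}

# pixel sizes: argument override > sidecar > TIFF resolution tags > error
resolve_pixel_sizes <- function(px, py, meta, info, path) {
  if (is.null(px) && !is.null(meta$pixel_size_x)) px <- meta$pixel_size_x
  if (is.null(py) && !is.null(meta$pixel_size_y)) py <- meta$pixel_size_y
  if ((is.null(px) || is.null(py)) && !is.null(info$x.resolution)) {
    unit_um <- switch(as.character(info$resolution.unit %||% "none"),
                      inch = 25400, cm = 10000, 1)
    if (is.null(px)) px <- unit_um / info$x.resolution
    if (is.null(py))
      py <- unit_um / (info$y.resolution %||% info$x.resolution)
  }
  if (is.null(px) || is.null(py))
    stop("pixel size unknown for ", path,
         ": no override, no sidecar, no TIFF resolution metadata")
  list(x = px, y = py)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- ImageJ .roi polyline codec ---------------------------------------------
# Binary layout (big-endian): "Iout" magic, version short, type byte at 6
# (5 = polyline), bounds shorts at 8..15, n at 16..17, options short at 50..51
# (bit 128 = sub-pixel resolution). Integer coordinates (2n + 2n shorts,
# relative to left/top) start at byte 64; when the sub-pixel flag is set, float
# absolute coordinates (4n + 4n bytes) follow at byte 64 + 4n.

ROI_TYPE_POLYLINE <- 5L
ROI_OPT_SUBPIXEL <- 128L

read_roi_polyline <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ .roi file: ", path)
  be_short <- function(off, n = 1L, signed = TRUE)
    readBin(raw[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
            endian = "big", signed = signed)
  type <- as.integer(raw[7])
  if (type != ROI_TYPE_POLYLINE)
    stop("ROI type ", type, " is not a polyline/segmented line")
  top <- be_short(8); left <- be_short(10)
  n <- be_short(16, signed = FALSE)
  if (n < 2) stop("polyline ROI has fewer than 2 vertices")
  opts <- be_short(50, signed = FALSE)
  if (bitwAnd(opts, ROI_OPT_SUBPIXEL) != 0 && length(raw) >= 64 + 12 * n) {
    off <- 64 + 4 * n
    xs <- readBin(raw[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
                  endian = "big")
    ys <- readBin(raw[(off + 4 * n + 1):(off + 8 * n)], "numeric", n = n,
                  size = 4, endian = "big")
  } else {
    xs <- be_short(64, n) + left
    ys <- be_short(64 + 2 * n, n) + top
  }
  cbind(x = xs, y = ys)
}

write_roi_polyline <- function(points_px, path) {
  n <- nrow(points_px)
  xs <- points_px[, 1]; ys <- points_px[, 2]
  left <- floor(min(xs)); top <- floor(min(ys))
  xi <- as.integer(round(xs)) - as.integer(left)
  yi <- as.integer(round(ys)) - as.integer(top)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  wshort <- function(v) writeBin(as.integer(v), con, size = 2, endian = "big")
  wshort(227)                                    # version
  writeBin(as.raw(c(ROI_TYPE_POLYLINE, 0)), con) # type + pad
  wshort(c(top, left, ceiling(max(ys)) + 1, ceiling(max(xs)) + 1, n))
  writeBin(raw(32), con)                         # bytes 18..49
  wshort(ROI_OPT_SUBPIXEL)                       # options at 50
  writeBin(raw(12), con)                         # bytes 52..63
  wshort(xi); wshort(yi)
  writeBin(xs, con, size = 4, endian = "big")
  writeBin(ys, con, size = 4, endian = "big")
  invisible(path)
}
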