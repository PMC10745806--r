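# Shaft-band excision, density binning, and transverse/longitudinal mean
# profiles; group stacks with AVG/MAX projections.
#
# The excised band is flagged, never deleted, so transverse positions keep
# their physical meaning (a visible gap at the shaft). Densities are per um^2:
# foreground pixels (or intensity) summed over 4-pixel transverse bins and
# divided by the bin area.

#' Excise the central shaft band from a straightened image or mask
#'
#' Columns within `band_um / 2` of the centre column (where the axonal shaft
#' lies) are flagged excluded; all other pixels are untouched. Excluded
#' pixels contribute to no downstream average, density or count.
#'
#' @param image An `axo_straightened` or `axo_mask`.
#' @param band_um Full width of the excised band (um, default 5).
#' @return The same object with the band flagged invalid and a `band_um`
#'   field recorded.
#' @export
remove_shaft_band <- function(image, band_um = 5) {
  stopifnot(is_str_geometry(image))
  if (band_um >= image$width_um)
    stop("band_um must be smaller than the straightened width")
  cc <- centre_column(image)
  off <- (seq_len(ncol(image$pixels)) - cc) * image$pixel_size_x
  band_cols <- abs(off) <= band_um / 2
  image$valid[, band_cols] <- FALSE
  image$band_um <- band_um
  image
}

#' Bin a mask (or straightened image) into densities per square micrometre
#'
#' Transverse bins of `bin_px` consecutive columns are laid out from the
#' edges of the excised shaft band outwards (partial bins at the image edges
#' are dropped, as are bins that would straddle the band). For a mask, a
#' cell's value is its foreground-pixel count divided by the cell area
#' (collaterals / um^2); for a straightened image it is the summed intensity
#' divided by the cell area. Cells containing any invalid pixel are excluded.
#'
#' @param mask An `axo_mask` (or `axo_straightened` for intensity densities)
#'   with the shaft band already excised ([remove_shaft_band()]).
#' @param bin_px Number of columns per transverse bin (default 4).
#' @return An `axo_density` grid: `values` (rows = along-axon positions,
#'   columns = bins; NA where excluded), `excluded`, `positions_x` (signed um
#'   offsets of bin centres), `positions_y` (um from the proximal end),
#'   `bin_cols` (columns of every bin), `bin_width_x_um`, `cell_area_um2`,
#'   `source`.
#' @export
density_grid <- function(mask, bin_px = 4L) {
  stopifnot(is_str_geometry(mask))
  if (bin_px < 1L) stop("bin_px must be >= 1")
  px <- mask$pixels
  nr <- nrow(px); nc <- ncol(px)
  psx <- mask$pixel_size_x; psy <- mask$pixel_size_y
  cc <- centre_column(mask)
  band_um <- mask$band_um %||% 0
  off <- (seq_len(nc) - cc) * psx
  band_cols <- which(abs(off) <= band_um / 2)
  left_edge <- if (length(band_cols)) min(band_cols) - 1L else 0L
  right_edge <- if (length(band_cols)) max(band_cols) + 1L else 1L

  bins <- list()
  if (left_edge >= bin_px) {     # right-aligned against the band's left edge
    starts <- seq(left_edge - bin_px + 1L, 1L, by = -bin_px)
    starts <- starts[starts >= 1L]
    for (s in rev(starts)) bins <- c(bins, list(s:(s + bin_px - 1L)))
  }
  if (nc - right_edge + 1L >= bin_px) {   # left-aligned against right edge
    starts <- seq(right_edge, nc - bin_px + 1L, by = bin_px)
    for (s in starts) bins <- c(bins, list(s:(s + bin_px - 1L)))
  }
  if (!length(bins)) stop("no complete transverse bin fits outside the band")

  area <- bin_px * psx * psy
  values <- matrix(NA_real_, nr, length(bins))
  excluded <- matrix(TRUE, nr, length(bins))
  for (j in seq_along(bins)) {
    cols <- bins[[j]]
    ok <- rowSums(!mask$valid[, cols, drop = FALSE]) == 0L
    v <- rowSums(px[, cols, drop = FALSE])
    values[ok, j] <- v[ok] / area
    excluded[, j] <- !ok
  }
  structure(
    list(values = values, excluded = excluded,
         positions_x = vapply(bins, function(cols) mean(off[cols]), 0),
         positions_y = (seq_len(nr) - 1) * psy,
         bin_cols = bins,
         bin_width_x_um = bin_px * psx,
         cell_area_um2 = area,
         pixel_size_y = psy,
         source = if (inherits(mask, "axo_mask")) "mask" else "intensity"),
    class = "axo_density")
}

#' Transverse mean profile over a group of density grids
#'
#' For every transverse bin, the mean density over all along-axon positions
#' of all images (excluded cells omitted). Per-image means are retained as
#' the observations for group statistics.
#'
#' @param grids List of `axo_density` grids sharing bin geometry.
#' @return An `axo_profile` with `axis = "transverse"`, `positions` = signed
#'   bin-centre offsets from the shaft centre (um), pooled `values`,
#'   `per_image` matrix, and per-position valid-cell counts `n_cells`.
#' @export
transverse_profile <- function(grids) {
  grids <- check_grid_group(grids)
  pos <- grids[[1]]$positions_x
  per_image <- do.call(rbind, lapply(grids, function(g)
    colMeans(g$values, na.rm = TRUE)))
  per_image[is.nan(per_image)] <- NA_real_
  sums <- Reduce(`+`, lapply(grids, function(g) {
    v <- g$values; v[is.na(v)] <- 0; colSums(v)
  }))
  ns <- Reduce(`+`, lapply(grids, function(g) colSums(!g$excluded)))
  new_profile("transverse", pos, sums / pmax(ns, 1), ns, per_image,
              grids[[1]]$source)
}

#' Longitudinal mean profile over a group of density grids
#'
#' For every along-axon position, the mean density over all transverse bins
#' of all images reaching that position (shorter images are omitted from that
#' position's mean; the contributing cell count is tracked).
#'
#' @param grids List of `axo_density` grids sharing bin geometry.
#' @return An `axo_profile` with `axis = "longitudinal"`, `positions` =
#'   distance from the proximal end (um).
#' @export
longitudinal_profile <- function(grids) {
  grids <- check_grid_group(grids)
  nrmax <- max(vapply(grids, function(g) nrow(g$values), 0L))
  psy <- grids[[1]]$pixel_size_y
  pos <- (seq_len(nrmax) - 1) * psy
  sums <- numeric(nrmax); ns <- numeric(nrmax)
  per_image <- matrix(NA_real_, length(grids), nrmax)
  for (i in seq_along(grids)) {
    v <- grids[[i]]$values
    rows <- seq_len(nrow(v))
    m <- rowMeans(v, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    per_image[i, rows] <- m
    v0 <- v; v0[is.na(v0)] <- 0
    sums[rows] <- sums[rows] + rowSums(v0)
    ns[rows] <- ns[rows] + rowSums(!grids[[i]]$excluded)
  }
  new_profile("longitudinal", pos, sums / pmax(ns, 1), ns, per_image,
              grids[[1]]$source)
}

#' Stack straightened images or masks and project them
#'
#' Images are top-aligned (proximal ends registered) and padded to the
#' longest image with excluded pixels; the average and maximum projections
#' are taken per pixel over valid entries only.
#'
#' @param images List of `axo_straightened` or list of `axo_mask` objects
#'   sharing column count (no mixing of the two types).
#' @return List of class `axo_stack_summary`: `stack` (the padded pixel
#'   arrays), `valid`, `avg_projection`, `max_projection`, `n` (valid entries
#'   per pixel; projections are NA where n = 0).
#' @export
stack_and_project <- function(images) {
  if (!length(images)) stop("empty image list")
  is_mask <- vapply(images, inherits, TRUE, what = "axo_mask")
  if (!all(is_mask) && any(is_mask))
    stop("cannot mix straightened images and masks in one stack")
  ncs <- vapply(images, function(x) ncol(x$pixels), 0L)
  if (length(unique(ncs)) != 1L) stop("images must share column count")
  nrmax <- max(vapply(images, function(x) nrow(x$pixels), 0L))
  nc <- ncs[1]
  pad <- function(m, fill) rbind(m, matrix(fill, nrmax - nrow(m), nc))
  stack <- lapply(images, function(x) pad(x$pixels, 0))
  valid <- lapply(images, function(x) pad(x$valid, FALSE))
  n <- Reduce(`+`, valid)
  ssum <- Reduce(`+`, Map(function(p, v) p * v, stack, valid))
  avg <- ssum / n
  avg[n == 0] <- NA_real_
  mx <- Reduce(pmax, Map(function(p, v) {
    p[!v] <- -Inf
    p
  }, stack, valid))
  mx[n == 0] <- NA_real_
  structure(list(stack = stack, valid = valid, avg_projection = avg,
                 max_projection = mx, n = n,
                 type = if (all(is_mask)) "mask" else "intensity"),
            class = "axo_stack_summary")
}

# ---- internal ---------------------------------------------------------------

new_profile <- function(axis, positions, values, n_cells, per_image, source) {
  values[n_cells == 0] <- NA_real_
  structure(
    list(axis = axis, positions = positions, values = values,
         n_cells = n_cells, per_image = per_image,
         n_images = nrow(per_image), source = source),
    class = "axo_profile")
}

#' @export
print.axo_profile <- function(x, ...) {
  cat(sprintf("<axo_profile> %s, %d positions, %d images (source: %s)\n",
              x$axis, length(x$positions), x$n_images, x$source))
  invisible(x)
}

check_grid_group <- function(grids) {
  if (inherits(grids, "axo_density")) grids <- list(grids)
  if (!length(grids)) stop("empty grid list")
  stopifnot(all(vapply(grids, inherits, TRUE, what = "axo_density")))
  p1 <- grids[[1]]$positions_x
  for (g in grids[-1]) {
    if (length(g$positions_x) != length(p1) ||
        max(abs(g$positions_x - p1)) > 1e-9)
      stop("density grids do not share bin geometry")
  }
  grids
}
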