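# Trace geometry and straightening of the axon into a fixed-width band image.

#' Polyline length of an axon trace
#'
#' Sum of Euclidean lengths of consecutive segments, in micrometres. Works for
#' 2D and 3D traces; for a 3D trace this is the full three-dimensional path
#' length (always at least as long as the length of its 2D projection).
#'
#' @param trace An [axon_trace()].
#' @return Length in um.
#' @export
trace_length <- function(trace) {
  stopifnot(inherits(trace, "axo_trace"))
  d <- diff(trace$vertices)
  sum(sqrt(rowSums(d * d)))
}

#' Project a 3D trace onto the imaging plane
#'
#' Drops the z coordinate; consecutive vertices that become coincident after
#' projection are merged. Projection never increases the path length.
#'
#' @param trace A 3D [axon_trace()].
#' @return A 2D [axon_trace()].
#' @export
project_to_2d <- function(trace) {
  stopifnot(inherits(trace, "axo_trace"))
  if (ncol(trace$vertices) != 3L) stop("trace is already 2D")
  v <- trace$vertices[, c("x", "y"), drop = FALSE]
  keep <- c(TRUE, rowSums(diff(v)^2) > 0)
  axon_trace(v[keep, , drop = FALSE])
}

#' Straighten an image along an axon trace
#'
#' Resamples the source image along the manual axon trace into a band image:
#' rows run along the axon (row 1 = proximal end), columns run transversely
#' with the trace on the exact centre column. The path is resampled at uniform
#' arc-length steps equal to the source `pixel_size_y`; unit tangents come
#' from central differences of the resampled path, and the transverse
#' direction is the tangent rotated so that, for a trace running down the
#' image, positive offsets point towards +x. Sampling is bilinear; samples
#' falling outside the source are zero-filled and flagged invalid.
#'
#' @param image A [planar_image()] (e.g. the maximum intensity projection).
#' @param trace A 2D [axon_trace()] in micrometres.
#' @param width_um Full transverse width of the band (um); the column count is
#'   `width_um / pixel_size_x` rounded to the nearest odd integer so that a
#'   centre column exists.
#' @return An `axo_straightened` image with fields `pixels`, `valid`
#'   (in-bounds flags), `width_um` and `axon_length_um`.
#' @export
straighten_image <- function(image, trace, width_um = 25) {
  stopifnot(inherits(image, "axo_image"), inherits(trace, "axo_trace"))
  if (ncol(trace$vertices) != 2L)
    stop("straightening needs a 2D trace; use project_to_2d first")
  if (!is.numeric(width_um) || width_um <= 0) stop("width_um must be > 0")
  psx <- image$pixel_size_x
  psy <- image$pixel_size_y
  L <- trace_length(trace)
  if (L <= 0) stop("degenerate zero-length trace")

  path <- resample_polyline(trace$vertices, psy)   # rows: along-axon samples
  nr <- nrow(path)
  tang <- central_diff_tangents(path)
  # transverse unit vector: tangent rotated -90 deg ((tx,ty) -> (ty,-tx)),
  # so a downward-running trace has positive offsets towards +x
  normal <- cbind(tang[, 2], -tang[, 1])

  nc <- max(2L * as.integer(round((width_um / psx - 1) / 2)) + 1L, 1L)
  offs <- (seq_len(nc) - (nc + 1L) / 2) * psx     # signed um offsets

  # sample coordinates in um, then to 0-based pixel coordinates
  sx <- outer(path[, 1], rep(1, nc)) + outer(normal[, 1], offs)
  sy <- outer(path[, 2], rep(1, nc)) + outer(normal[, 2], offs)
  samp <- bilinear_sample(image$pixels, sx / psx, sy / psy)
  new_straightened(samp$values, samp$valid, psx, psy, width_um, L)
}

# Resample a polyline (n x 2 matrix, um) at uniform arc-length steps `step`,
# from the first vertex; the end vertex is included only if it falls on a step.
resample_polyline <- function(v, step) {
  seg <- diff(v)
  seglen <- sqrt(rowSums(seg * seg))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(v) - 1L)
  frac <- (s - cum[idx]) / seglen[idx]
  v[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
}

central_diff_tangents <- function(p) {
  n <- nrow(p)
  if (n == 1L) return(matrix(c(0, 1), 1))
  fwd <- rbind(p[-1, , drop = FALSE], p[n, , drop = FALSE])
  bwd <- rbind(p[1, , drop = FALSE], p[-n, , drop = FALSE])
  t <- fwd - bwd
  len <- sqrt(rowSums(t * t))
  len[len == 0] <- 1
  t / len
}

# Bilinear interpolation of `img` at 0-based pixel coordinates (x = column,
# y = row); out-of-bounds samples give value 0 and valid = FALSE.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  dm <- dim(x)
  x <- as.vector(x); y <- as.vector(y)
  valid <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1
  x0 <- floor(x); y0 <- floor(y)
  # clamp so corner indices stay in range; fractional parts preserve exactness
  x0 <- pmin(pmax(x0, 0), nc - 1); y0 <- pmin(pmax(y0, 0), nr - 1)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- pmin(pmax(x - x0, 0), 1); fy <- pmin(pmax(y - y0, 0), 1)
  at <- function(r, c) img[cbind(r + 1, c + 1)]
  v <- (1 - fy) * ((1 - fx) * at(y0, x0) + fx * at(y0, x1)) +
       fy * ((1 - fx) * at(y1, x0) + fx * at(y1, x1))
  v[!valid] <- 0
  list(values = matrix(v, dm[1], dm[2]), valid = matrix(valid, dm[1], dm[2]))
}
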