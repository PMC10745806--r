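# STR -> binary collateral mask: automatic thresholding, skeletonization,
# and removal of components not longer than the minimum collateral length.
#
# Component "length" is a physical geodesic: pixels are nodes of an
# 8-connected graph with edge weights pixel_size_x, pixel_size_y, or their
# Euclidean diagonal, and a component's length is the largest shortest-path
# distance between any two of its pixels. The minimum-length rule is strict:
# a component of exactly the minimum length is removed.

#' Threshold a straightened image
#'
#' Default is Otsu's method on the histogram of valid pixels (the automatic
#' threshold of common fluorescence workflows). Out-of-bounds (invalid)
#' pixels are always background. A constant image yields an empty foreground
#' under `otsu` rather than an error.
#'
#' @param str_image An `axo_straightened` image (or any `axo_image`).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold intensity for `method = "fixed"`; foreground
#'   is `pixels >= fixed_value`.
#' @return Integer 0/1 matrix with attribute `threshold`.
#' @export
threshold_image <- function(str_image, method = c("otsu", "fixed"),
                            fixed_value = NULL) {
  method <- match.arg(method)
  px <- str_image$pixels
  valid <- str_image$valid %||% matrix(TRUE, nrow(px), ncol(px))
  if (!all(is.finite(px))) stop("non-finite intensities")
  if (method == "fixed") {
    if (is.null(fixed_value)) stop("fixed thresholding needs fixed_value")
    thr <- fixed_value
    fg <- px >= thr
  } else {
    vals <- px[valid]
    if (length(vals) == 0L || max(vals) == min(vals)) {
      thr <- if (length(vals)) max(vals) else 0
      fg <- matrix(FALSE, nrow(px), ncol(px))
    } else {
      thr <- EBImage::otsu(EBImage::Image(px * valid),
                           range = range(vals), levels = 256L)
      fg <- px > thr
    }
  }
  fg <- fg & valid
  out <- matrix(as.integer(fg), nrow(px), ncol(px))
  attr(out, "threshold") <- as.numeric(thr)
  out
}

#' Skeletonize a binary image
#'
#' Zhang-Suen thinning: iteratively peels boundary pixels until a one-pixel-
#' wide, 8-connected skeleton remains. The number of 8-connected components
#' is preserved.
#'
#' @param binary Integer/logical 0/1 matrix.
#' @return Integer 0/1 matrix of the same size.
#' @export
skeletonize_mask <- function(binary) {
  m <- matrix(as.integer(binary != 0), nrow(binary), ncol(binary))
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  core_r <- 2:(nr + 1); core_c <- 2:(nc + 1)
  nb <- function(p, dr, dc) p[core_r + dr, core_c + dc]
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- nb(pad, -1, 0); p3 <- nb(pad, -1, 1); p4 <- nb(pad, 0, 1)
      p5 <- nb(pad, 1, 1);  p6 <- nb(pad, 1, 0);  p7 <- nb(pad, 1, -1)
      p8 <- nb(pad, 0, -1); p9 <- nb(pad, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- pad[core_r, core_c] == 1L & b >= 2 & b <= 6 & a == 1
      if (phase == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        tmp <- pad[core_r, core_c]
        tmp[cond] <- 0L
        pad[core_r, core_c] <- tmp
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[core_r, core_c]
}

#' Remove skeleton components not longer than a minimum physical length
#'
#' Each 8-connected component's length is its maximum geodesic path length
#' over the pixel graph (diagonal-aware edge weights). Components whose
#' length is less than or equal to `min_collateral_um` are removed — strictly
#' "longer than" survives, so a component of exactly the minimum is dropped.
#'
#' @param skeleton Integer/logical 0/1 matrix (1-px-wide skeleton).
#' @param min_collateral_um Minimum collateral length in um (default 0.5).
#' @param pixel_size_x,pixel_size_y Pixel sizes in um.
#' @return Integer 0/1 matrix.
#' @export
filter_short_components <- function(skeleton, min_collateral_um = 0.5,
                                    pixel_size_x, pixel_size_y) {
  m <- matrix(as.integer(skeleton != 0), nrow(skeleton), ncol(skeleton))
  comp <- skeleton_components(m, pixel_size_x, pixel_size_y)
  if (comp$n == 0L) return(m)
  drop_ids <- which(comp$lengths <= min_collateral_um)
  if (length(drop_ids)) m[comp$labels %in% drop_ids] <- 0L
  m
}

#' Label skeleton components and measure their geodesic lengths
#'
#' @param pixels 0/1 matrix.
#' @param pixel_size_x,pixel_size_y Pixel sizes in um.
#' @return List: `n` components, `labels` (matrix, 0 = background),
#'   `lengths` (um per component, max geodesic path), `sizes` (pixel counts).
#' @export
skeleton_components <- function(pixels, pixel_size_x, pixel_size_y) {
  idx <- which(pixels != 0)
  labels <- matrix(0L, nrow(pixels), ncol(pixels))
  if (length(idx) == 0L)
    return(list(n = 0L, labels = labels, lengths = numeric(0),
                sizes = integer(0)))
  g <- pixel_graph(pixels, pixel_size_x, pixel_size_y)
  cmp <- igraph::components(g)
  labels[idx] <- cmp$membership
  lens <- vapply(seq_len(cmp$no), function(ci) {
    vids <- which(cmp$membership == ci)
    if (length(vids) == 1L) return(0)
    d <- igraph::distances(g, v = vids, to = vids)
    max(d)
  }, numeric(1))
  list(n = cmp$no, labels = labels, lengths = lens,
       sizes = as.integer(cmp$csize))
}

# Weighted 8-neighbour pixel adjacency graph over foreground pixels.
pixel_graph <- function(pixels, psx, psy) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  idx <- which(pixels != 0)
  vid <- matrix(0L, nr, nc)
  vid[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  edges <- integer(0)
  weights <- numeric(0)
  offs <- list(c(0L, 1L, psx), c(1L, 0L, psy),
               c(1L, 1L, sqrt(psx^2 + psy^2)),
               c(-1L, 1L, sqrt(psx^2 + psy^2)))
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- pixels[cbind(r2[ok], c2[ok])] != 0
    if (any(ok)) {
      edges <- c(edges, rbind(vid[cbind(rows[ok], cols[ok])],
                              vid[cbind(r2[ok], c2[ok])]))
      weights <- c(weights, rep(o[3], sum(ok)))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, edges, weight = weights)
  g
}

#' Build a collateral mask from a straightened image
#'
#' Composition of [threshold_image()], [skeletonize_mask()] and
#' [filter_short_components()], producing the binary mask of collaterals
#' longer than `min_collateral_um`.
#'
#' @param str_image An `axo_straightened` image.
#' @param min_collateral_um Minimum collateral length in um (default 0.5).
#' @param threshold `"otsu"` (default) or `"fixed"`.
#' @param fixed_value Intensity threshold when `threshold = "fixed"`.
#' @return An `axo_mask` in the same straightened geometry.
#' @export
make_mask <- function(str_image, min_collateral_um = 0.5,
                      threshold = c("otsu", "fixed"), fixed_value = NULL) {
  stopifnot(is_str_geometry(str_image))
  bin <- threshold_image(str_image, threshold, fixed_value)
  skel <- skeletonize_mask(bin)
  filt <- filter_short_components(skel, min_collateral_um,
                                  str_image$pixel_size_x,
                                  str_image$pixel_size_y)
  new_mask(filt, str_image$valid, str_image$pixel_size_x,
           str_image$pixel_size_y, str_image$width_um,
           str_image$axon_length_um, min_collateral_um)
}

#' Count 8-connected foreground components of a mask
#'
#' Only valid (in-bounds, non-excluded) foreground pixels are counted; after
#' shaft-band excision this is the number of detected collaterals.
#'
#' @param mask An `axo_mask`.
#' @return Integer component count.
#' @export
count_components <- function(mask) {
  stopifnot(inherits(mask, "axo_mask"))
  fg <- mask$pixels * (mask$valid)
  skeleton_components(fg, mask$pixel_size_x, mask$pixel_size_y)$n
}
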