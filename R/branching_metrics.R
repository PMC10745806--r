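# Scalar branching summaries per axon: collateral skeleton length normalized
# to axon length, with a dorsal (proximal, first 70 um) vs ventral split.

#' Branching summary of a collateral mask
#'
#' Collateral "length" is the summed physical length of the valid skeleton:
#' every 8-neighbour adjacency between two valid foreground pixels
#' contributes its Euclidean step length (the same diagonal-aware metric as
#' the component-length filter), shared half-and-half between its two pixels
#' so that regional totals add up exactly. Ratios are dimensionless
#' (um of collateral per um of axon):
#' * `total_branching` = total collateral length / axon length,
#' * `dorsal_branching` = collateral length within the first
#'   `dorsal_extent_um` of the axon / `dorsal_extent_um`,
#' * `ventral_branching` = remaining collateral length /
#'   (axon length - `dorsal_extent_um`), reported as `NA` when the axon is
#'   not longer than the dorsal extent.
#'
#' @param mask An `axo_mask` with the shaft band excised.
#' @param dorsal_extent_um Length of the dorsal (proximal) region in um
#'   (default 70).
#' @return An object of class `axo_branching` with the ratios, the raw
#'   regional collateral lengths (um) and the component count.
#' @export
branching_summary <- function(mask, dorsal_extent_um = 70) {
  stopifnot(inherits(mask, "axo_mask"))
  L <- mask$axon_length_um
  if (is.null(L) || !is.finite(L) || L <= 0) stop("axon_length_um unknown")
  w <- pixel_length_weights(mask)
  rowpos <- (seq_len(nrow(mask$pixels)) - 1) * mask$pixel_size_y
  dorsal_rows <- rowpos < dorsal_extent_um
  total_um <- sum(w)
  dorsal_um <- sum(w[dorsal_rows, , drop = FALSE])
  ventral_um <- total_um - dorsal_um
  ventral <- if (L > dorsal_extent_um) ventral_um / (L - dorsal_extent_um)
             else NA_real_
  structure(
    list(axon_length_um = L,
         dorsal_extent_um = dorsal_extent_um,
         total_branching = total_um / L,
         dorsal_branching = dorsal_um / dorsal_extent_um,
         ventral_branching = ventral,
         total_collateral_um = total_um,
         dorsal_collateral_um = dorsal_um,
         ventral_collateral_um = ventral_um,
         n_components = count_components(mask)),
    class = "axo_branching")
}

#' @export
print.axo_branching <- function(x, ...) {
  cat(sprintf(paste0("<axo_branching> axon %.1f um, total %.3f, dorsal %.3f,",
                     " ventral %s, %d components\n"),
              x$axon_length_um, x$total_branching, x$dorsal_branching,
              if (is.na(x$ventral_branching)) "NA"
              else sprintf("%.3f", x$ventral_branching),
              x$n_components))
  invisible(x)
}

# Per-pixel physical length contribution: half the summed Euclidean lengths
# of the pixel's incident valid-skeleton edges. Summing over any pixel set
# partitions the total edge length exactly.
pixel_length_weights <- function(mask) {
  fg <- mask$pixels != 0 & mask$valid
  nr <- nrow(fg); nc <- ncol(fg)
  psx <- mask$pixel_size_x; psy <- mask$pixel_size_y
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- fg
  core_r <- 2:(nr + 1); core_c <- 2:(nc + 1)
  diag <- sqrt(psx^2 + psy^2)
  w <- matrix(0, nr, nc)
  offs <- list(c(-1, 0, psy), c(1, 0, psy), c(0, -1, psx), c(0, 1, psx),
               c(-1, -1, diag), c(-1, 1, diag), c(1, -1, diag), c(1, 1, diag))
  for (o in offs)
    w <- w + pad[core_r + o[1], core_c + o[2]] * (o[3] / 2)
  w * fg
}
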