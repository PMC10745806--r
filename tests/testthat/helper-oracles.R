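# Independent oracles and fixture builders used across the suite. Everything
# here is deliberately brute-force and separate from the package's own
# implementation paths.

# Build a mask object directly from a 0/1 matrix (bypasses thresholding).
make_test_mask <- function(pixels, psx = 0.25, psy = 0.25,
                           axon_length_um = (nrow(pixels) - 1) * psy,
                           width_um = ncol(pixels) * psx,
                           band_um = NULL) {
  m <- axoquant:::new_mask(pixels,
                           matrix(TRUE, nrow(pixels), ncol(pixels)),
                           psx, psy, width_um, axon_length_um, 0.5)
  if (!is.null(band_um)) m <- remove_shaft_band(m, band_um)
  m
}

make_test_str <- function(pixels, psx = 0.25, psy = 0.25,
                          axon_length_um = (nrow(pixels) - 1) * psy,
                          width_um = ncol(pixels) * psx) {
  axoquant:::new_straightened(pixels,
                              matrix(TRUE, nrow(pixels), ncol(pixels)),
                              psx, psy, width_um, axon_length_um)
}

# All-pairs shortest paths over the 8-connected foreground pixel graph by
# Floyd-Warshall; returns per-component maximum geodesic length and the
# component count (components found by label propagation on the distance
# matrix).
fw_component_lengths <- function(pixels, psx, psy) {
  idx <- which(pixels != 0)
  n <- length(idx)
  if (n == 0) return(numeric(0))
  nr <- nrow(pixels)
  rows <- ((idx - 1) %% nr) + 1
  cols <- ((idx - 1) %/% nr) + 1
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) {
    dr <- rows - rows[i]; dc <- cols - cols[i]
    adj <- abs(dr) <= 1 & abs(dc) <= 1 & !(dr == 0 & dc == 0)
    w <- sqrt((dc * psx)^2 + (dr * psy)^2)
    D[i, adj] <- w[adj]
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[is.finite(D[i, ])] <- cid
    }
  }
  vapply(seq_len(cid), function(ci) {
    d <- D[comp == ci, comp == ci, drop = FALSE]
    max(d[is.finite(d)])
  }, numeric(1))
}

# Exhaustive-scan Otsu: among 256 candidate cut levels, the threshold
# maximizing the between-class variance of the partition (x < t | x >= t).
otsu_bruteforce <- function(values) {
  rng <- range(values)
  cands <- seq(rng[1], rng[2], length.out = 258)[2:257]
  best <- cands[1]; best_v <- -Inf
  n <- length(values)
  for (t in cands) {
    lo <- values[values < t]; hi <- values[values >= t]
    if (!length(lo) || !length(hi)) next
    v <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best <- t }
  }
  best
}

# Brute-force BH step-up: scan every observed p as a candidate cutoff.
brute_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= (seq_len(m) / m) * q)
  rej <- rep(FALSE, m)
  if (length(ok)) rej[ord[seq_len(max(ok))]] <- TRUE
  rej
}

# Exact Mann-Whitney U distribution by full enumeration of rank assignments.
enumerate_u <- function(n1, n2) {
  N <- n1 + n2
  combs <- utils::combn(N, n1)
  apply(combs, 2, function(a) sum(a) - n1 * (n1 + 1) / 2)
}

# A size-n1 subset of 1..N whose ranks give Mann-Whitney U = u.
ranks_for_u <- function(n1, n2, u) {
  N <- n1 + n2
  a <- seq_len(n1)            # U = 0 configuration
  need <- u
  for (i in rev(seq_len(n1))) {
    step <- min(need, N - n1) # how far element i can be pushed up
    a[i] <- a[i] + step
    need <- need - step
    if (need == 0) break
  }
  stopifnot(sum(a) - n1 * (n1 + 1) / 2 == u, !anyDuplicated(a))
  a
}
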