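# Seeded synthetic axon phantoms with machine-readable ground truth.
#
# A phantom is a bright, gently curved shaft with lateral collaterals of
# controlled position / side / length / angle, an optional terminal arbor,
# Gaussian ridge cross-sections rendered analytically from distance-to-
# segment (no rasterized line artifacts), plus background, Gaussian noise
# and optional Poisson resampling. Presets emulate the three biological
# regimes of interest: a sparse early axon (~70 um, a few short
# collaterals), a dense later axon (~140 um, many ventrally biased
# collaterals with a terminal arbor), and an aberrant regime with dense
# ectopic dorsal collaterals.

#' Specify a synthetic axon phantom
#'
#' @param canvas_px Image size as `c(rows, cols)`.
#' @param pixel_size_x,pixel_size_y Pixel sizes (um/pixel). The default
#'   0.2483 um/px makes a 4-pixel transverse bin exactly 0.9932 um wide.
#' @param shaft List: `control_points` (n x 2 matrix, um, proximal first),
#'   `sigma_um` (Gaussian ridge half-width), `peak` (intensity).
#' @param collaterals Data frame with columns `position_um` (arc position
#'   along the shaft), `side` ("left"/"right"), `length_um`, `angle_deg`
#'   (from the local shaft normal, towards distal), `intensity`. May be
#'   empty.
#' @param arbor Optional terminal arbor: list `at_um` (arc position of the
#'   centre), `n_segments`, `radius_um`, `intensity`.
#' @param background Background intensity level.
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @param poisson If TRUE, intensities are Poisson-resampled after noise.
#' @param seed Integer seed fixing the rendered image bit-exactly.
#' @return An object of class `axo_phantom_spec`.
#' @export
phantom_spec <- function(canvas_px = c(400L, 161L),
                         pixel_size_x = 0.2483, pixel_size_y = 0.2483,
                         shaft = list(
                           control_points = rbind(c(20, 2), c(20, 90)),
                           sigma_um = 0.4, peak = 200),
                         collaterals = empty_collaterals(),
                         arbor = NULL,
                         background = 10, noise_sd = 0, poisson = FALSE,
                         seed = 1L) {
  check_pixel_sizes(pixel_size_x, pixel_size_y)
  stopifnot(length(canvas_px) == 2L, all(canvas_px >= 8L))
  shaft$control_points <- as.matrix(shaft$control_points)
  stopifnot(ncol(shaft$control_points) == 2L,
            nrow(shaft$control_points) >= 2L,
            shaft$sigma_um > 0, shaft$peak > 0)
  collaterals <- as.data.frame(collaterals)
  needed <- c("position_um", "side", "length_um", "angle_deg", "intensity")
  if (!all(needed %in% names(collaterals)))
    stop("collaterals need columns: ", paste(needed, collapse = ", "))
  L <- polyline_len(shaft$control_points)
  if (nrow(collaterals)) {
    if (any(collaterals$length_um <= 0)) stop("collateral lengths must be > 0")
    if (any(collaterals$position_um < 0 | collaterals$position_um > L))
      stop("collateral positions must lie within [0, shaft length]")
    if (!all(collaterals$side %in% c("left", "right")))
      stop("collateral side must be 'left' or 'right'")
  }
  structure(
    list(canvas_px = as.integer(canvas_px),
         pixel_size_x = pixel_size_x, pixel_size_y = pixel_size_y,
         shaft = shaft, collaterals = collaterals, arbor = arbor,
         background = background, noise_sd = noise_sd, poisson = poisson,
         seed = as.integer(seed), shaft_length_um = L),
    class = "axo_phantom_spec")
}

#' An empty collateral table
#' @return Zero-row data frame with the collateral columns.
#' @export
empty_collaterals <- function() {
  data.frame(position_um = numeric(0), side = character(0),
             length_um = numeric(0), angle_deg = numeric(0),
             intensity = numeric(0))
}

#' Render a phantom image with its trace and ground truth
#'
#' @param spec An [phantom_spec()].
#' @param dorsal_extent_um Boundary (um) used for the truth's dorsal/ventral
#'   collateral-length split (default 70).
#' @return List: `image` (a [planar_image()]), `trace` (the shaft
#'   [axon_trace()], the stand-in for the manual axonal contour), and
#'   `truth` (class `axo_phantom_truth`: collateral count, per-collateral
#'   table, total/dorsal/ventral collateral length at the stated boundary,
#'   analytic shaft length).
#' @export
generate_phantom <- function(spec, dorsal_extent_um = 70) {
  stopifnot(inherits(spec, "axo_phantom_spec"))
  nr <- spec$canvas_px[1]; nc <- spec$canvas_px[2]
  psx <- spec$pixel_size_x; psy <- spec$pixel_size_y
  margin <- 3 * spec$shaft$sigma_um
  xmax <- (nc - 1) * psx; ymax <- (nr - 1) * psy

  segs <- shaft_segments(spec$shaft)
  cl <- spec$collaterals
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      pt <- polyline_point(spec$shaft$control_points, cl$position_um[i])
      side_vec <- if (cl$side[i] == "right") pt$normal else -pt$normal
      ang <- cl$angle_deg[i] * pi / 180
      dir <- cos(ang) * side_vec + sin(ang) * pt$tangent
      tip <- pt$point + cl$length_um[i] * dir
      if (any(tip < margin) || tip[1] > xmax - margin || tip[2] > ymax - margin)
        stop(sprintf("collateral %d (tip %.1f, %.1f um) extends outside the canvas",
                     i, tip[1], tip[2]))
      segs <- rbind(segs, c(pt$point, tip, spec$shaft$sigma_um,
                            cl$intensity[i]))
    }
  }
  if (!is.null(spec$arbor)) {
    ab <- spec$arbor
    ctr <- polyline_point(spec$shaft$control_points, ab$at_um)
    angles <- seq(0, 2 * pi, length.out = ab$n_segments + 1L)[-1]
    for (a in angles) {
      tip <- ctr$point + ab$radius_um * c(cos(a), sin(a))
      tip <- pmin(pmax(tip, margin), c(xmax, ymax) - margin)
      segs <- rbind(segs, c(ctr$point, tip, spec$shaft$sigma_um,
                            ab$intensity))
    }
  }

  img <- render_ridges(nr, nc, psx, psy, segs, spec$background)
  if (spec$noise_sd > 0 || spec$poisson) {
    img <- with_seed(spec$seed, {
      v <- img
      if (spec$noise_sd > 0)
        v <- v + stats::rnorm(length(v), sd = spec$noise_sd)
      if (spec$poisson) v <- stats::rpois(length(v), pmax(v, 0))
      matrix(pmax(v, 0), nr, nc)
    })
  }

  boundary <- dorsal_extent_um
  dorsal_len <- if (nrow(cl)) sum(cl$length_um[cl$position_um < boundary]) else 0
  truth <- structure(
    list(collateral_count = nrow(cl),
         collaterals = cl,
         total_collateral_um = if (nrow(cl)) sum(cl$length_um) else 0,
         dorsal_collateral_um = dorsal_len,
         ventral_collateral_um =
           (if (nrow(cl)) sum(cl$length_um) else 0) - dorsal_len,
         dorsal_extent_um = boundary,
         shaft_length_um = spec$shaft_length_um),
    class = "axo_phantom_truth")
  list(image = planar_image(img, psx, psy),
       trace = axon_trace(spec$shaft$control_points),
       truth = truth)
}

#' Phantom presets for the three study regimes
#'
#' `sparse_24hpf`: ~70 um shaft with 2-4 short collaterals. `dense_48hpf`:
#' ~140 um shaft with 10-20 collaterals biased ventral (positions beyond
#' 70 um) plus a terminal arbor. `aberrant`: ~75 um shaft carrying dense
#' ectopic dorsal collaterals. Collateral lengths start at 4 um so that
#' every collateral reaches well beyond the 5 um shaft excision band.
#'
#' @param regime One of `"sparse_24hpf"`, `"dense_48hpf"`, `"aberrant"`.
#' @param seed Integer seed; fixes the sampled spec and the rendered noise.
#' @param noise_sd Gaussian noise SD (default 20, i.e. SNR 10 against the
#'   200-intensity shaft).
#' @return An [phantom_spec()].
#' @export
phantom_preset <- function(regime = c("sparse_24hpf", "dense_48hpf",
                                      "aberrant"),
                           seed = 1L, noise_sd = 20) {
  regime <- match.arg(regime)
  with_seed(seed, {
    L <- switch(regime,
                sparse_24hpf = stats::runif(1, 66, 74),
                dense_48hpf = stats::runif(1, 134, 146),
                aberrant = stats::runif(1, 70, 80))
    n_coll <- switch(regime,
                     sparse_24hpf = sample(2:4, 1),
                     dense_48hpf = sample(10:20, 1),
                     aberrant = sample(8:14, 1))
    pos <- switch(regime,
                  sparse_24hpf = sort(stats::runif(n_coll, 8, L - 6)),
                  dense_48hpf = sort(c(
                    stats::runif(max(round(n_coll * 0.2), 1), 8, 65),
                    stats::runif(n_coll - max(round(n_coll * 0.2), 1),
                                 72, L - 8))),
                  aberrant = sort(stats::runif(n_coll, 8, min(68, L - 6))))
    n_coll <- length(pos)
    # keep collateral roots >= 2 um apart so detected components stay separate
    pos <- enforce_min_gap(pos, 2, 8, L - 6)
    lens <- switch(regime,
                   sparse_24hpf = stats::runif(n_coll, 4, 8),
                   dense_48hpf = stats::runif(n_coll, 4, 11),
                   aberrant = stats::runif(n_coll, 4, 10))
    canvas_rows <- ceiling((L + 12) / 0.2483)
    curve_amp <- stats::runif(1, 1, 3)
    ys <- seq(4, 4 + L, length.out = 40)
    xs <- 20 + curve_amp * sin(seq(0, 2.2 * pi, length.out = 40))
    spec <- phantom_spec(
      canvas_px = c(canvas_rows, 161L),
      shaft = list(control_points = cbind(xs, ys), sigma_um = 0.4,
                   peak = 200),
      collaterals = data.frame(
        position_um = pos,
        side = sample(c("left", "right"), n_coll, replace = TRUE),
        length_um = lens,
        angle_deg = stats::runif(n_coll, -25, 25),
        intensity = stats::runif(n_coll, 120, 180)),
      arbor = if (regime == "dense_48hpf")
        list(at_um = NA, n_segments = 5L, radius_um = 7, intensity = 150)
        else NULL,
      background = 10, noise_sd = noise_sd, poisson = FALSE,
      seed = seed)
    if (!is.null(spec$arbor))
      spec$arbor$at_um <- spec$shaft_length_um - 8
    spec
  })
}

#' Evaluate the RNG-dependent expression under a fixed seed
#'
#' Saves and restores the global RNG state so phantom generation never
#' perturbs a caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# ---- internal ---------------------------------------------------------------

polyline_len <- function(v) {
  d <- diff(v)
  sum(sqrt(rowSums(d * d)))
}

# point, unit tangent and unit normal at arc position s along polyline v
polyline_point <- function(v, s) {
  seg <- diff(v)
  seglen <- sqrt(rowSums(seg * seg))
  cum <- c(0, cumsum(seglen))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(1L, min(findInterval(s, cum, rightmost.closed = TRUE),
                   nrow(v) - 1L))
  t <- seg[i, ] / seglen[i]
  list(point = v[i, ] + (s - cum[i]) * t,
       tangent = t,
       normal = c(t[2], -t[1]))
}

shaft_segments <- function(shaft) {
  v <- shaft$control_points
  n <- nrow(v)
  cbind(v[-n, 1], v[-n, 2], v[-1, 1], v[-1, 2],
        shaft$sigma_um, shaft$peak)
}

# Analytic Gaussian ridge rendering: each segment row is
# (x1, y1, x2, y2, sigma, peak); intensity at a pixel is background plus the
# maximum over segments of peak * exp(-d^2 / (2 sigma^2)), d = distance from
# the pixel centre to the segment. Only pixels within 4 sigma of a segment's
# bounding box are touched.
render_ridges <- function(nr, nc, psx, psy, segs, background) {
  img <- matrix(background, nr, nc)
  if (is.null(dim(segs)) || nrow(segs) == 0L) return(img)
  for (i in seq_len(nrow(segs))) {
    x1 <- segs[i, 1]; y1 <- segs[i, 2]; x2 <- segs[i, 3]; y2 <- segs[i, 4]
    sg <- segs[i, 5]; pk <- segs[i, 6]
    reach <- 4 * sg
    cmin <- max(1L, floor((min(x1, x2) - reach) / psx) + 1L)
    cmax <- min(nc, ceiling((max(x1, x2) + reach) / psx) + 1L)
    rmin <- max(1L, floor((min(y1, y2) - reach) / psy) + 1L)
    rmax <- min(nr, ceiling((max(y1, y2) + reach) / psy) + 1L)
    if (cmin > cmax || rmin > rmax) next
    X <- outer(rep(1, rmax - rmin + 1L), (seq(cmin, cmax) - 1L) * psx)
    Y <- outer((seq(rmin, rmax) - 1L) * psy, rep(1, cmax - cmin + 1L))
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    tt <- if (len2 > 0) pmin(pmax(((X - x1) * dx + (Y - y1) * dy) / len2,
                                  0), 1) else 0
    d2 <- (X - (x1 + tt * dx))^2 + (Y - (y1 + tt * dy))^2
    contrib <- background + pk * exp(-d2 / (2 * sg^2))
    sub <- img[rmin:rmax, cmin:cmax]
    img[rmin:rmax, cmin:cmax] <- pmax(sub, contrib)
  }
  img
}

enforce_min_gap <- function(pos, gap, lo, hi) {
  pos <- sort(pos)
  for (i in seq_along(pos)[-1]) {
    if (pos[i] - pos[i - 1] < gap) pos[i] <- pos[i - 1] + gap
  }
  pmin(pos, hi)
}
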