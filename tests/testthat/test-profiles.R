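test_that("shaft-band excision flags the centre, leaves the rest untouched", {
  set.seed(51)
  px <- matrix(rbinom(80 * 101, 1, 0.1), 80, 101)
  m <- make_test_mask(px, psx = 0.2483, psy = 0.2483)
  mb <- remove_shaft_band(m, 5)
  off <- (1:101 - 51) * 0.2483
  expect_true(all(!mb$valid[, abs(off) <= 2.5]))
  expect_true(all(mb$valid[, abs(off) > 2.5]))
  # remaining analyzed width ~ 20 um
  analyzed <- sum(abs(off) > 2.5) * 0.2483
  expect_lt(abs(analyzed - 20), 2 * 0.2483)
  # pixels bit-identical outside the band
  expect_identical(mb$pixels, m$pixels)
  expect_error(remove_shaft_band(m, 30), "smaller than")
})

test_that("density grid implements the per-bin formula and conserves counts", {
  # single foreground pixel at the reference pixel size
  px <- matrix(0L, 40, 101)
  px[10, 70] <- 1L
  m <- make_test_mask(px, psx = 0.2483, psy = 0.2483, band_um = 5)
  g <- density_grid(m, 4)
  expect_equal(g$bin_width_x_um, 0.9932)
  v <- g$values[10, ]
  expect_equal(sum(v > 0), 1)
  expect_equal(max(v), 1 / (4 * 0.2483 * 0.2483), tolerance = 1e-12)
  expect_equal(sum(g$values * g$cell_area_um2, na.rm = TRUE), 1)
  # empty mask -> all-zero grid
  g0 <- density_grid(make_test_mask(matrix(0L, 40, 101), band_um = 5), 4)
  expect_true(all(g0$values[!g0$excluded] == 0))
  # conservation against a brute-force pixel count on random masks
  set.seed(52)
  for (i in 1:5) {
    px <- matrix(rbinom(60 * 101, 1, 0.15), 60, 101)
    m <- make_test_mask(px, band_um = 5)
    g <- density_grid(m, 4)
    covered <- 0
    for (j in seq_along(g$bin_cols))
      covered <- covered + sum(px[!g$excluded[, j], g$bin_cols[[j]]])
    expect_equal(sum(g$values * g$cell_area_um2, na.rm = TRUE), covered)
  }
  expect_error(density_grid(make_test_mask(px, band_um = 5), 0), "bin_px")
})

test_that("bins never straddle the excised band", {
  m <- make_test_mask(matrix(1L, 10, 101), psx = 0.2483, psy = 0.2483,
                      band_um = 5)
  g <- density_grid(m, 4)
  off <- (1:101 - 51) * 0.2483
  band_cols <- which(abs(off) <= 2.5)
  for (cols in g$bin_cols) {
    expect_equal(length(cols), 4)
    expect_length(intersect(cols, band_cols), 0)
  }
  expect_true(all(abs(g$positions_x) > 2.5))
})

test_that("transverse and longitudinal profiles match brute-force means", {
  set.seed(53)
  masks <- lapply(1:3, function(i)
    make_test_mask(matrix(rbinom(50 * 101, 1, 0.1), 50, 101), band_um = 5))
  grids <- lapply(masks, density_grid, bin_px = 4)
  tp <- transverse_profile(grids)
  lp <- longitudinal_profile(grids)
  # brute-force pooled means
  allv <- do.call(rbind, lapply(grids, `[[`, "values"))
  for (j in seq_along(tp$positions))
    expect_equal(tp$values[j], mean(allv[, j], na.rm = TRUE))
  for (r in seq_along(lp$positions)) {
    vals <- unlist(lapply(grids, function(g)
      if (r <= nrow(g$values)) g$values[r, ] else NULL))
    expect_equal(lp$values[r], mean(vals, na.rm = TRUE))
  }
  expect_equal(tp$n_images, 3)
  expect_true(all(diff(tp$positions) > 0))
  expect_true(all(diff(lp$positions) > 0))
})

test_that("uniform grids give flat profiles and averaging is linear", {
  mk <- function(val) {
    g <- density_grid(make_test_mask(matrix(0L, 30, 101), band_um = 5), 4)
    g$values[!g$excluded] <- val
    g
  }
  tp1 <- transverse_profile(list(mk(3)))
  expect_true(all(abs(tp1$values - 3) < 1e-12))
  tp2 <- transverse_profile(list(mk(3), mk(7)))
  expect_true(all(abs(tp2$values - 5) < 1e-12))
  lp2 <- longitudinal_profile(list(mk(3), mk(7)))
  expect_true(all(abs(lp2$values - 5) < 1e-12))
})

test_that("weighted profile means agree with the grand mean density", {
  set.seed(54)
  grids <- lapply(1:4, function(i) {
    nr <- sample(40:70, 1)  # unequal axon lengths
    density_grid(make_test_mask(matrix(rbinom(nr * 101, 1, 0.12), nr, 101),
                                band_um = 5), 4)
  })
  tp <- transverse_profile(grids)
  lp <- longitudinal_profile(grids)
  grand <- sum(unlist(lapply(grids, function(g) g$values[!g$excluded]))) /
    sum(unlist(lapply(grids, function(g) sum(!g$excluded))))
  expect_equal(sum(tp$values * tp$n_cells, na.rm = TRUE) / sum(tp$n_cells),
               grand, tolerance = 1e-12)
  expect_equal(sum(lp$values * lp$n_cells, na.rm = TRUE) / sum(lp$n_cells),
               grand, tolerance = 1e-12)
})

test_that("stacking top-aligns, pads with exclusions, and projects correctly", {
  set.seed(55)
  a <- make_test_str(matrix(runif(30 * 21), 30, 21))
  # single image: AVG = MAX = the image
  s1 <- stack_and_project(list(a))
  expect_equal(s1$avg_projection, a$pixels)
  expect_equal(s1$max_projection, a$pixels)
  # two identical images
  s2 <- stack_and_project(list(a, a))
  expect_equal(s2$avg_projection, a$pixels)
  expect_equal(s2$max_projection, a$pixels)
  # unequal lengths vs a brute-force loop honouring padding
  b <- make_test_str(matrix(runif(20 * 21), 20, 21))
  s3 <- stack_and_project(list(a, b))
  for (r in c(1, 10, 20, 25, 30)) for (cc in c(1, 11, 21)) {
    vals <- c(a$pixels[r, cc], if (r <= 20) b$pixels[r, cc])
    expect_equal(s3$avg_projection[r, cc], mean(vals))
    expect_equal(s3$max_projection[r, cc], max(vals))
  }
  expect_error(stack_and_project(list(a, make_test_mask(matrix(0L, 5, 21)))),
               "mix")
})
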