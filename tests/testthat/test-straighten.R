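test_that("trace length matches brute-force segment summation and basic cases", {
  expect_equal(trace_length(axon_trace(cbind(c(0, 0), c(0, 10)))), 10)
  expect_equal(trace_length(axon_trace(cbind(c(0, 3), c(0, 4)))), 5)
  set.seed(31)
  for (i in 1:20) {
    dims <- sample(2:3, 1)
    v <- matrix(runif(10 * dims, 0, 100), 10, dims)
    tr <- axon_trace(v)
    oracle <- 0
    for (k in 2:10) oracle <- oracle + sqrt(sum((v[k, ] - v[k - 1, ])^2))
    expect_equal(trace_length(tr), oracle, tolerance = 1e-12)
  }
})

test_that("trace length is invariant under rigid rotation and translation", {
  set.seed(32)
  v <- matrix(runif(16, 0, 50), 8, 2)
  tr <- axon_trace(v)
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  v2 <- sweep(v %*% R, 2, c(13.7, -4.2), `+`)
  expect_equal(trace_length(axon_trace(v2)), trace_length(tr),
               tolerance = 1e-10)
})

test_that("2D projection contracts length and merges coincident vertices", {
  expect_equal(project_to_2d(axon_trace(rbind(c(0, 0, 0), c(0, 10, 0))))$vertices,
               cbind(x = c(0, 0), y = c(0, 10)))
  # helix: projected length equals the dropped-z polyline, and never exceeds 3D
  t <- seq(0, 2 * pi, length.out = 8)
  helix <- axon_trace(cbind(cos(t), sin(t), t))
  proj <- project_to_2d(helix)
  v2 <- cbind(cos(t), sin(t))
  oracle <- sum(sqrt(rowSums(diff(v2)^2)))
  expect_equal(trace_length(proj), oracle, tolerance = 1e-12)
  expect_lte(trace_length(proj), trace_length(helix))
  # vertices that coincide after dropping z are merged
  stacked <- axon_trace(rbind(c(0, 0, 0), c(0, 0, 5), c(3, 4, 5)))
  expect_equal(nrow(project_to_2d(stacked)$vertices), 2)
  expect_error(project_to_2d(project_to_2d(helix)), "already 2D")
})

test_that("a straight vertical trace reproduces the axis-aligned crop exactly", {
  set.seed(33)
  img <- planar_image(matrix(runif(150 * 80, 0, 255), 150, 80), 0.25, 0.25)
  tr <- axon_trace(cbind(x = c(10, 10), y = c(5, 30)))  # column 41, rows 21..121
  st <- straighten_image(img, tr, width_um = 8)
  nc <- ncol(st$pixels)
  expect_equal(nc %% 2, 1)
  half <- (nc - 1) / 2
  crop <- img$pixels[21:(21 + nrow(st$pixels) - 1), (41 - half):(41 + half)]
  expect_equal(st$pixels, crop, tolerance = 1e-10)
  expect_true(all(st$valid))
  expect_equal(st$axon_length_um, 25)
})

test_that("a constant image straightens to a constant band", {
  img <- planar_image(matrix(7, 100, 100), 0.25, 0.25)
  tr <- axon_trace(cbind(x = c(12, 10, 13), y = c(4, 10, 18)))
  st <- straighten_image(img, tr, width_um = 10)
  expect_equal(max(abs(st$pixels[st$valid] - 7)), 0, tolerance = 1e-9)
})

test_that("a bright traced arc lands on the centre column of the band", {
  # quarter-circle arc of radius 60 px rendered with a gaussian cross-section
  ps <- 0.25
  n <- 220
  xs <- (0:(n - 1)) * ps
  grid_x <- matrix(xs, n, n, byrow = TRUE)
  grid_y <- matrix(xs, n, n)
  r <- sqrt((grid_x - 5)^2 + (grid_y - 5)^2)
  img <- planar_image(exp(-(r - 30)^2 / (2 * 0.35^2)) * 100 + 1e-6, ps, ps)
  th <- seq(0, pi / 2, length.out = 60)
  tr <- axon_trace(cbind(x = 5 + 30 * sin(th), y = 5 + 30 * cos(th)))
  st <- straighten_image(img, tr, width_um = 10)
  cc <- (ncol(st$pixels) + 1) / 2
  for (row in seq(2, nrow(st$pixels) - 1, by = 7)) {
    w <- st$pixels[row, ]
    centroid <- sum(w * seq_along(w)) / sum(w)
    expect_lt(abs(centroid - cc), 1)
  }
})

test_that("straightening is equivariant under a 90-degree rotation", {
  set.seed(34)
  img <- planar_image(matrix(runif(160 * 120, 0, 100), 160, 120), 0.25, 0.25)
  tr <- axon_trace(cbind(x = c(15, 14, 16, 15), y = c(5, 12, 22, 35)))
  st <- straighten_image(img, tr, width_um = 10)
  # rotate image clockwise: new(x, y) = (H - old_y, old_x)
  H <- (nrow(img$pixels) - 1) * img$pixel_size_y
  rot <- planar_image(t(img$pixels)[, nrow(img$pixels):1], 0.25, 0.25)
  trr <- axon_trace(cbind(x = H - tr$vertices[, "y"], y = tr$vertices[, "x"]))
  st2 <- straighten_image(rot, trr, width_um = 10)
  expect_equal(dim(st2$pixels), dim(st$pixels))
  mae <- mean(abs(st2$pixels - st$pixels))
  expect_lt(mae / diff(range(st$pixels)), 0.01)
})

test_that("band geometry: odd column count, physical area, validity flags", {
  img <- planar_image(matrix(1, 120, 30), 0.2483, 0.2483)
  tr <- axon_trace(cbind(x = c(3.5, 3.5), y = c(2, 26)))
  st <- straighten_image(img, tr, width_um = 25)
  expect_equal(ncol(st$pixels), 101)  # 25 / 0.2483 rounded to odd
  expect_equal(nrow(st$pixels), floor(st$axon_length_um / 0.2483) + 1)
  area <- ncol(st$pixels) * st$pixel_size_x * nrow(st$pixels) * st$pixel_size_y
  expect_lt(abs(area - 25 * st$axon_length_um),
            25 * st$pixel_size_y + st$axon_length_um * st$pixel_size_x + 1)
  # the 25 um band exceeds the 7.5 um wide image: margins are flagged, zero
  expect_true(any(!st$valid))
  expect_true(all(st$pixels[!st$valid] == 0))
  expect_error(straighten_image(img, tr, width_um = -1), "width_um")
})
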