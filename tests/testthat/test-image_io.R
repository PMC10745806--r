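test_that("stack round trips are lossless for integers and <1e-6 for floats", {
  dir <- withr::local_tempdir()
  # integer 16-bit
  set.seed(11)
  vox <- array(sample(0:65535, 4 * 6 * 3, replace = TRUE), c(4, 6, 3))
  st <- image_stack(vox, 0.25, 0.25, 1.0)
  p <- file.path(dir, "s16.tif")
  write_stack(st, p, bits = 16L)
  back <- read_stack(p)
  expect_identical(back$voxels, st$voxels * 1)
  expect_equal(back$pixel_size_x, 0.25)
  expect_equal(back$pixel_size_y, 0.25)
  expect_equal(back$z_step, 1.0)
  # float 32-bit
  voxf <- array(runif(4 * 6 * 2, 0, 1234.5), c(4, 6, 2))
  stf <- image_stack(voxf, 0.1, 0.2, 0.5)
  pf <- file.path(dir, "f32.tif")
  write_stack(stf, pf, bits = 32L)
  backf <- read_stack(pf)
  expect_lt(max(abs(backf$voxels - voxf) / pmax(voxf, 1e-12)), 1e-6)
})

test_that("trivial stack fields survive a round trip", {
  dir <- withr::local_tempdir()
  st <- image_stack(array(0, c(4, 4, 1)), 0.25, 0.25, 1.0)
  p <- file.path(dir, "z.tif")
  write_stack(st, p, bits = 8L)
  back <- read_stack(p)
  expect_equal(dim(back$voxels), c(4, 4, 1))
  expect_true(all(back$voxels == 0))
})

test_that("missing pixel size is an explicit error, overrides always win", {
  dir <- withr::local_tempdir()
  st <- image_stack(array(1, c(4, 4, 1)), 0.3, 0.4, 1)
  p <- file.path(dir, "a.tif")
  write_stack(st, p)
  file.remove(axoquant:::sidecar_path(p))  # strip metadata
  expect_error(read_stack(p), "pixel size unknown")
  ov <- read_stack(p, pixel_size_x = 0.5, pixel_size_y = 0.6)
  expect_equal(c(ov$pixel_size_x, ov$pixel_size_y), c(0.5, 0.6))
  # override beats sidecar
  write_stack(st, p)
  ov2 <- read_stack(p, pixel_size_x = 0.9, pixel_size_y = 0.9)
  expect_equal(ov2$pixel_size_x, 0.9)
})

test_that("an independent TIFF reader sees the same 16-bit voxel data", {
  dir <- withr::local_tempdir()
  set.seed(21)
  vox <- array(sample(0:65535, 8 * 8 * 2, replace = TRUE), c(8, 8, 2))
  p <- file.path(dir, "chk.tif")
  write_stack(image_stack(vox, 0.25, 0.25, 1), p, bits = 16L)
  out <- system2("python", c("-c", shQuote(paste0(
    "import tifffile, numpy as np;",
    "a = tifffile.imread('", p, "').astype('int64');",
    "print(int(a.sum()), int(a.max()), a.shape[0])"))),
    stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(vals[1], sum(vox))
  expect_equal(vals[2], max(vox))
  expect_equal(vals[3], 2)
})

test_that("max projection equals a brute-force per-pixel loop over z", {
  set.seed(5)
  vox <- array(runif(5 * 12 * 12, 0, 100), c(12, 12, 5))
  st <- image_stack(vox, 0.25, 0.25, 1)
  mip <- max_project(st)
  oracle <- matrix(0, 12, 12)
  for (r in 1:12) for (c in 1:12) {
    m <- -Inf
    for (k in 1:5) m <- max(m, vox[r, c, k])
    oracle[r, c] <- m
  }
  expect_equal(mip$pixels, oracle)
  # single-slice identity and dominance
  one <- image_stack(vox[, , 1, drop = FALSE], 0.25, 0.25, 1)
  expect_equal(max_project(one)$pixels, vox[, , 1])
  dom <- vox; dom[, , 3] <- 1000
  expect_true(all(max_project(image_stack(dom, 0.25, 0.25, 1))$pixels == 1000))
  # idempotent on its own output, commutes with squaring
  expect_equal(max_project(image_stack(mip$pixels, 0.25, 0.25, 1))$pixels,
               mip$pixels)
  sq <- max_project(image_stack(vox^2, 0.25, 0.25, 1))
  expect_equal(sq$pixels, mip$pixels^2)
})

test_that("CSV traces convert pixel coordinates to micrometres", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.csv")
  writeLines(c("0,0", "0,40"), p)
  tr <- read_trace(p, 0.25, 0.25, units = "px")
  expect_equal(tr$vertices, cbind(x = c(0, 0), y = c(0, 10)))
  # header + um units round trip through the package writer
  tr2 <- axon_trace(cbind(x = c(1.5, 3.25, 7), y = c(2, 8.5, 9)))
  p2 <- file.path(dir, "t2.csv")
  write_trace(tr2, p2)
  back <- read_trace(p2, 0.25, 0.25, units = "um")
  expect_equal(back$vertices, tr2$vertices)
})

test_that("ImageJ .roi polylines round trip and decode a reference byte layout", {
  dir <- withr::local_tempdir()
  tr <- axon_trace(cbind(x = c(1.25, 2.5, 10), y = c(0.25, 6.5, 12.75)))
  p <- file.path(dir, "t.roi")
  write_trace(tr, p, pixel_size_x = 0.25, pixel_size_y = 0.25)
  back <- read_trace(p, 0.25, 0.25)
  expect_equal(back$vertices, tr$vertices, tolerance = 1e-6)

  # fixture composed by hand from the published binary layout: integer-
  # coordinate polyline with 7 vertices, left = 3, top = 2
  xs <- c(0L, 2L, 5L, 9L, 14L, 20L, 27L)
  ys <- c(0L, 3L, 1L, 6L, 2L, 8L, 4L)
  con <- file(file.path(dir, "ref.roi"), "wb")
  writeBin(charToRaw("Iout"), con)
  writeBin(c(227L, 5L * 256L), con, size = 2, endian = "big") # version, type byte
  writeBin(c(2L, 3L, 11L, 31L, 7L), con, size = 2, endian = "big")
  writeBin(raw(46), con)                                      # up to byte 64
  writeBin(c(xs, ys), con, size = 2, endian = "big")
  close(con)
  ref <- read_trace(file.path(dir, "ref.roi"), 1, 1)
  expect_equal(ref$vertices[, "x"], xs + 3)
  expect_equal(ref$vertices[, "y"], ys + 2)

  # a non-polyline type is rejected
  bad <- readBin(file.path(dir, "ref.roi"), "raw", 200)
  bad[7] <- as.raw(1)  # rectangle
  writeBin(bad, file.path(dir, "bad.roi"))
  expect_error(read_trace(file.path(dir, "bad.roi"), 1, 1), "not a polyline")
})

test_that("profile TSVs have a position header, one row per image, and round trip", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "p.tsv")
  write_profiles_tsv(list(c(0.5, 1.25, 2)), p, positions = c(-2, 0, 2))
  lines <- readLines(p)
  expect_length(lines, 2)
  expect_equal(strsplit(lines[1], "\t")[[1]], c("-2", "0", "2"))
  # two-profile fixture against a hand-written expected file
  write_profiles_tsv(list(c(1, 2.5), c(0.125, 4)), p, positions = c(1, 2))
  expect_equal(readLines(p), c("1\t2", "1\t2.5", "0.125\t4"))
  back <- read_profiles_tsv(p)
  expect_equal(back$positions, c(1, 2))
  expect_equal(back$values, rbind(c(1, 2.5), c(0.125, 4)))
  expect_error(write_profiles_tsv(list(1:2, 1:3), p, positions = 1:2),
               "share length")
})
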