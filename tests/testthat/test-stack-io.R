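test_that("multi-page and directory volumes load identically, (z,y,x) order", {
  d <- withr::local_tempdir()
  set.seed(1)
  planes <- lapply(1:5, function(i) matrix(sample(0:65535, 120, TRUE), 10, 12))
  tiff::writeTIFF(lapply(planes, function(m) m / 65535),
                  file.path(d, "stack.tif"), bits.per.sample = 16L)
  v <- load_volume(file.path(d, "stack.tif"), c(1, 0.5, 0.5), "ZO-1")
  expect_identical(dim(v$data), c(5L, 10L, 12L))
  expect_true(all(v$data[3, , ] == planes[[3]]))
  expect_equal(v$channel_name, "ZO-1")

  dir.create(file.path(d, "planes"))
  for (i in 1:5)
    tiff::writeTIFF(planes[[i]] / 65535,
                    file.path(d, "planes", sprintf("z%02d.tif", i)),
                    bits.per.sample = 16L)
  v2 <- load_volume(file.path(d, "planes"), c(1, 0.5, 0.5))
  expect_true(all(v2$data == v$data))

  # single-plane file gives a degenerate (1, H, W) stack
  tiff::writeTIFF(planes[[1]] / 65535, file.path(d, "one.tif"),
                  bits.per.sample = 16L)
  v3 <- load_volume(file.path(d, "one.tif"), c(1, 1, 1))
  expect_identical(dim(v3$data), c(1L, 10L, 12L))
})

test_that("ragged plane sizes raise an error naming the offending plane", {
  d <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0, 10, 12), file.path(d, "z00.tif"))
  tiff::writeTIFF(matrix(0, 5, 5), file.path(d, "z01.tif"))
  expect_error(load_volume(d, c(1, 1, 1)), "z01")
  expect_error(load_volume(file.path(d, "missing.tif"), c(1, 1, 1)),
               "no such")
})

test_that("volume constructor enforces invariants", {
  a <- array(1, dim = c(2, 3, 4))
  expect_error(voxel_volume(a, c(0, 1, 1)), "positive")
  expect_error(voxel_volume(array(-1, dim = c(1, 1, 1)), c(1, 1, 1)),
               "nonnegative")
  expect_error(voxel_volume(matrix(1, 2, 2), c(1, 1, 1)), "3D")
})

test_that("integer sheets round-trip bit-exactly with full metadata", {
  d <- withr::local_tempdir()
  sh <- unwrapped_sheet(matrix(as.numeric(sample(0:65535, 20000, TRUE)),
                               200, 100),
                        c(0.5, 0.4), list(radius = 80.25, projection = "max"))
  f <- file.path(d, "sheet.tif")
  save_sheet(sh, f)
  sh2 <- load_sheet(f)
  expect_true(all(sh2$data == sh$data))
  expect_identical(sh2$pixel_size, c(0.5, 0.4))
  expect_equal(sh2$provenance$radius, 80.25)
})

test_that("float sheets round-trip to float32 precision", {
  d <- withr::local_tempdir()
  sh <- unwrapped_sheet(matrix(runif(100) * 123.4, 10, 10), c(1, 1))
  f <- file.path(d, "sheetf.tif")
  save_sheet(sh, f)
  sh2 <- load_sheet(f)
  expect_lt(max(abs(sh2$data - sh$data) / pmax(sh$data, 1e-9)), 1e-6)
})

test_that("missing sidecar requires explicit pixel sizes", {
  d <- withr::local_tempdir()
  sh <- unwrapped_sheet(matrix(as.numeric(1:100), 10, 10), c(1, 1))
  f <- file.path(d, "s.tif")
  save_sheet(sh, f)
  file.remove(paste0(f, ".json"))
  expect_error(load_sheet(f), "pixel_size")
  sh2 <- load_sheet(f, pixel_size = c(2, 3))
  expect_identical(sh2$pixel_size, c(2, 3))
  expect_true(all(sh2$data == sh$data))
})

test_that("waypoint files load with duplicate collapse and validation", {
  d <- withr::local_tempdir()
  ws <- waypoint_set(rbind(c(1, 2), c(1, 2), c(5, 6), c(9, 2)), "sheet",
                     closed = TRUE)
  expect_equal(nrow(ws$points), 3)  # consecutive duplicate collapsed
  f <- file.path(d, "wp.json")
  save_waypoints(ws, f)
  w <- load_waypoints(f)
  expect_equal(w$points, ws$points)
  expect_true(w$closed)
  expect_equal(w$frame, "sheet")

  ft <- file.path(d, "wp.txt")
  writeLines(c("1 2", "5 6", "9 2"), ft)
  w2 <- load_waypoints(ft, frame = "cross_section")
  expect_equal(nrow(w2$points), 3)
  expect_equal(w2$frame, "cross_section")

  expect_error(waypoint_set(rbind(c(1, 1), c(2, 2)), "sheet", closed = TRUE),
               "at least 3")
  expect_error(waypoint_set(rbind(c(1, Inf), c(2, 2), c(3, 3)), "sheet"),
               "finite")
})
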