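# Border on a uniform image along the outline of a square; side steps of
# `side` pixels give perimeter_px = 4 * side exactly.
square_border <- function(side = 10, origin = c(5, 5), img_size = 60) {
  img <- matrix(1, img_size, img_size)
  wp <- rbind(origin, origin + c(0, side), origin + c(side, side),
              origin + c(side, 0))
  trace_border(img, waypoint_set(wp, "sheet", closed = TRUE))
}

test_that("threshold isolation is a plain >= comparison", {
  img <- matrix(c(20, 180, 20, 180), 2, 2)
  expect_identical(isolate_junctions(img, 100), img >= 100)
  expect_true(all(isolate_junctions(img, 0)))
  expect_false(any(isolate_junctions(img, 181)))
  expect_equal(sum(isolate_junctions(img, 100)), 2)
})

test_that("otsu helper separates a bimodal image", {
  withr::with_seed(2, {
    img <- matrix(c(rnorm(500, 20, 3), rnorm(500, 180, 6)), 100, 10)
  })
  th <- otsu_threshold(pmax(img, 0))
  expect_gt(th, 40)
  expect_lt(th, 160)
})

test_that("a mask equal to the whole border is one full-loop segment", {
  b <- square_border(10)
  mask <- matrix(FALSE, 60, 60)
  mask[b$path] <- TRUE
  segs <- extract_segments(b, mask, default_config())
  expect_equal(nrow(segs), 1)
  expect_equal(segs$path_length_px, 40)          # full perimeter
  expect_equal(segs$thickness_px, 1)             # 40 px / L 40
  expect_equal(segs$ratio, 0.025)
  expect_equal(unname(junction_coverage(b, segs)["coverage_total"]), 1)
})

test_that("two disjoint 1-px runs give two segments with L = 20 and 6", {
  b <- square_border(30, origin = c(5, 5), img_size = 80)  # perimeter 120
  mask <- matrix(FALSE, 80, 80)
  mask[b$path[3:22, ]] <- TRUE    # 20 consecutive border pixels
  mask[b$path[40:45, ]] <- TRUE   # 6 consecutive border pixels
  segs <- extract_segments(b, mask, default_config())
  expect_equal(sort(segs$path_length_px), c(6, 20))
})

test_that("a thick blob's thickness equals area / run length", {
  b <- square_border(30, origin = c(20, 20), img_size = 80)
  mask <- matrix(FALSE, 80, 80)
  # blob of 12 x 5 = 60 px centered on the top border run (row 20)
  mask[15:26, 31:35] <- TRUE
  cfg <- classifier_config(1, corridor_halfwidth_px = 6)
  segs <- extract_segments(b, mask, cfg)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_pixels, 60)                # pixel-count oracle
  expect_equal(segs$path_length_px, 5)
  expect_equal(segs$thickness_px, 12)
  expect_equal(segs$ratio, 2.4)
  expect_equal(segs$phenotype, "perpendicular")
})

test_that("empty masks and single-point projections yield no segments", {
  b <- square_border(10)
  expect_equal(nrow(extract_segments(b, matrix(FALSE, 60, 60),
                                     default_config())), 0)
  mask <- matrix(FALSE, 60, 60)
  mask[b$path[1, 1], b$path[1, 2]] <- TRUE       # run of length 0
  expect_equal(nrow(extract_segments(b, mask, default_config())), 0)
})

test_that("the phenotype rule and its boundary conventions are exact", {
  cfg <- classifier_config(NA)
  expect_equal(classify_segment(20, 0.3, cfg), "continuous")
  expect_equal(classify_segment(10, 1.5, cfg), "perpendicular")
  expect_equal(classify_segment(10, 0.5, cfg), "punctate")
  # boundaries: L = 15 is not continuous; ratio = 1.2 is punctate
  expect_equal(classify_segment(15, 0.5, cfg), "punctate")
  expect_equal(classify_segment(15, 1.2, cfg), "punctate")
  expect_equal(classify_segment(15 + 1e-9, 2, cfg), "continuous")
  expect_equal(classify_segment(15, 1.2 + 1e-9, cfg), "perpendicular")
})

test_that("classification is monotone in L and ratio", {
  cfg <- classifier_config(NA)
  for (rho in c(0.1, 1.19, 1.21, 5)) {
    ph <- classify_segment(seq(1, 30, by = 0.5), rho, cfg)
    # once continuous, always continuous as L grows
    expect_true(all(diff(ph == "continuous") >= 0))
  }
  for (L in c(3, 10, 15)) {
    ph <- classify_segment(L, seq(0.1, 3, by = 0.1), cfg)
    # at fixed small L, growing rho never flips perpendicular -> punctate
    expect_true(all(diff(ph == "perpendicular") >= 0))
  }
})

test_that("coverage arithmetic: disjoint runs of 30 and 10 on perimeter 100", {
  # 40 x 10 rectangle: perimeter_px = 2 * (40 + 10) = 100
  img <- matrix(1, 70, 70)
  b <- trace_border(img, waypoint_set(rbind(c(10, 10), c(10, 50), c(20, 50),
                                            c(20, 10)), "sheet", TRUE))
  expect_equal(b$perimeter_px, 100)
  mask <- matrix(FALSE, 70, 70)
  mask[b$path[5:34, ]] <- TRUE                  # 30 px on the long side
  mask[b$path[61:70, ]] <- TRUE                 # 10 px on the other side
  cfg <- default_config()
  segs <- extract_segments(b, mask, cfg)
  cov <- junction_coverage(b, segs)
  expect_equal(unname(cov["coverage_continuous"]), 0.30)  # L = 30 > 15
  expect_equal(unname(cov["coverage_punctate"]), 0.10)    # L = 10, thin
  expect_equal(unname(cov["coverage_total"]), 0.40)
  expect_equal(sum(cov[1:3]), cov[["coverage_total"]])
})

test_that("no segments means zero coverage; zero perimeter is an error", {
  b <- square_border(10)
  cov <- junction_coverage(b, extract_segments(b, matrix(FALSE, 60, 60),
                                               default_config()))
  expect_true(all(cov == 0))
  b0 <- b
  b0$perimeter_px <- 0
  expect_error(junction_coverage(b0, data.frame()), "perimeter")
})

test_that("morphology anchors: square, rasterized circle, L-shape", {
  # 100 x 100 um square at 1 um pixels
  sq <- square_border(100, origin = c(3, 3), img_size = 110)
  m <- cell_morphology(sq, c(1, 1))
  expect_equal(unname(m["area_um2"]), 10000)
  expect_equal(unname(m["perimeter_um"]), 400)
  expect_equal(unname(m["circularity"]), 4 * pi * 1e4 / 16e4,
               tolerance = 1e-12)
  expect_equal(unname(m["solidity"]), 1)

  # rasterized circle, r = 50 px, vs continuous closed form pi r^2 / 2 pi r
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  wp <- round(cbind(60 + 50 * sin(th), 60 + 50 * cos(th)))
  cb <- trace_border(matrix(1, 120, 120), waypoint_set(wp, "sheet", TRUE))
  mc <- cell_morphology(cb, c(1, 1))
  expect_gt(unname(mc["circularity"]), 0.95)
  expect_lt(unname(mc["circularity"]), 1.10)
  expect_gte(unname(mc["solidity"]), 0.98)
  expect_equal(unname(mc["area_um2"]), pi * 50^2, tolerance = 0.02)

  # concave L: solidity equals the shoelace polygon / hull ratio
  wpL <- rbind(c(1, 1), c(1, 61), c(31, 61), c(31, 31), c(61, 31), c(61, 1))
  bL <- trace_border(matrix(1, 80, 80), waypoint_set(wpL, "sheet", TRUE))
  mL <- cell_morphology(bL, c(1, 1))
  expect_equal(unname(mL["solidity"]), (60 * 60 - 30 * 30) /
                 (60 * 60 - 30 * 30 / 2), tolerance = 1e-12)
})

test_that("morphology is scale-invariant and perimeter/area scale exactly", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  wp <- round(cbind(45 + 35 * sin(th), 45 + 35 * cos(th)))
  b <- trace_border(matrix(1, 90, 90), waypoint_set(wp, "sheet", TRUE))
  m1 <- cell_morphology(b, c(1, 1))
  m2 <- cell_morphology(b, c(2, 2))
  expect_equal(unname(m2["perimeter_um"] / m1["perimeter_um"]), 2)
  expect_equal(unname(m2["area_um2"] / m1["area_um2"]), 4)
  expect_equal(unname(m2["circularity"]), unname(m1["circularity"]),
               tolerance = 1e-12)
  expect_equal(unname(m2["solidity"]), unname(m1["solidity"]),
               tolerance = 1e-12)
})

test_that("self-intersecting borders are rejected with the crossing pixel", {
  fake <- square_border(10)
  fake$path <- rbind(fake$path, fake$path[5, , drop = FALSE])
  expect_error(cell_morphology(fake, c(1, 1)), "visited twice")
})

test_that("analyze_cells emits one tagged record per cell", {
  sc <- small_scene(3)
  cfg <- default_config()
  rec1 <- analyze_cells(sc$junction, sc$cells[1], cfg, channel_name = "ZO-1")
  expect_s3_class(rec1, "cell_records")
  expect_equal(nrow(rec1), 1)
  expect_equal(rec1$channel_name, "ZO-1")

  # blank channel: background only, all coverages zero
  blank <- sc$junction
  blank$data <- matrix(0, nrow(blank$data), ncol(blank$data))
  rec0 <- analyze_cells(blank, sc$cells, cfg)
  expect_true(all(rec0$coverage_total == 0))

  # errors are tagged with the failing cell id
  bad <- sc$cells[1]
  bad[[1]]$points[1, ] <- c(-3, -3)
  expect_error(analyze_cells(sc$junction, bad, cfg), "cell 1")
})
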