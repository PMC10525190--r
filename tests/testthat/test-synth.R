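test_that("scene generation is bit-identical under a fixed seed", {
  spec <- scene_spec(sheet_px = c(300, 300), grid = c(3, 3))
  a <- make_flat_monolayer(spec, seed = 7)
  b <- make_flat_monolayer(spec, seed = 7)
  expect_identical(a$junction$data, b$junction$data)
  expect_identical(a$nuclei$data, b$nuclei$data)
  expect_identical(a$truth$edges, b$truth$edges)
  c <- make_flat_monolayer(spec, seed = 8)
  expect_false(identical(a$junction$data, c$junction$data))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- runif(1)
  set.seed(123)
  invisible(make_flat_monolayer(scene_spec(sheet_px = c(200, 200),
                                           grid = c(2, 2)), seed = 5))
  expect_identical(runif(1), r1)
})

test_that("an all-continuous mix paints only long unbroken runs", {
  spec <- scene_spec(sheet_px = c(400, 400), grid = c(4, 4), mix = c(1, 0, 0))
  sc <- make_flat_monolayer(spec, seed = 2)
  ed <- sc$truth$edges
  expect_true(all(ed$phenotype == "continuous"))
  expect_true(all(ed$painted_len[ed$painted_len > 0] > 15))
  # and the pipeline sees only continuous segments
  mask <- isolate_junctions(sc$junction, 90)
  b <- trace_border(sc$junction, sc$cells[[6]])
  segs <- extract_segments(b, mask, default_config())
  expect_true(all(segs$phenotype == "continuous"))
})

test_that("a zero mix yields a background-only junction channel", {
  spec <- scene_spec(sheet_px = c(200, 200), grid = c(2, 2), mix = c(0, 0, 0))
  sc <- make_flat_monolayer(spec, seed = 1)
  expect_true(all(sc$junction$data == spec$background))
  expect_true(all(sc$truth$expected$coverage_total == 0))
})

test_that("ground truth obeys the coverage conservation rule", {
  ex <- small_scene(13)$truth$expected
  expect_equal(ex$coverage_continuous + ex$coverage_punctate +
                 ex$coverage_perpendicular, ex$coverage_total)
  expect_true(all(ex$coverage_total <= 1))
  expect_true(all(ex$coverage_total >= 0))
})

test_that("scene_spec validates its inputs", {
  expect_error(scene_spec(mix = c(0.7, 0.4, 0.2)), "at most 1")
  expect_error(scene_spec(mix = c(-0.1, 0, 0)), "at most 1")
  expect_error(scene_spec(radius = 0), "positive")
  expect_error(scene_spec(grid = c(0, 3)), "at least one cell")
  expect_error(scene_spec(background = -1), "nonnegative")
})

test_that("wrap_to_cylinder returns the true circle and checks geometry", {
  spec <- scene_spec(sheet_px = c(400, 60), grid = c(4, 1))
  sc <- make_flat_monolayer(spec, seed = 1)
  wr <- wrap_to_cylinder(sc$junction, spec)
  expect_equal(wr$circle$radius, 80)
  expect_equal(wr$circle$span, 2 * pi)
  expect_s3_class(wr$volume, "voxel_volume")
  # every cross-section of a wrapped uniform sheet shows an annulus
  uni <- sc$junction
  uni$data <- matrix(50, 400, 60)
  wu <- wrap_to_cylinder(uni, spec)
  cs <- extract_cross_section(wu$volume, 30)
  expect_true(all(abs(cs$data) < 1e-9 | abs(cs$data - 50) < 1e-9))
  expect_gt(sum(abs(cs$data - 50) < 1e-9), 400)

  # a sheet taller than the circumference is rejected
  tall <- scene_spec(sheet_px = c(400, 60), grid = c(4, 1), radius = 20)
  expect_error(wrap_to_cylinder(sc$junction, tall), "circumference")
})

test_that("disruption converts continuous runs and scales coverage down", {
  spec <- scene_spec(sheet_px = c(502, 400), grid = c(5, 4))
  base <- make_flat_monolayer(spec, seed = 42)

  expect_identical(make_disrupted_variant(base, 0), base)
  expect_error(make_disrupted_variant(base, 1.5), "0, 1")

  d1 <- make_disrupted_variant(base, 1)
  expect_true(all(d1$truth$edges$phenotype != "continuous"))
  expect_true(all(d1$truth$expected$coverage_continuous == 0))

  d5 <- make_disrupted_variant(base, 0.5)
  ratio <- mean(d5$truth$expected$coverage_continuous) /
    mean(base$truth$expected$coverage_continuous)
  expect_lt(abs(ratio - 0.5), 0.05)
  # tessellation is shared, only edge phenotypes change
  expect_identical(d5$truth$vertices, base$truth$vertices)
})
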