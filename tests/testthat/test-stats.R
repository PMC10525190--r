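test_that("K-squared matches independently computed reference values", {
  # reference values computed once with an independent implementation of the
  # same omnibus test (scipy.stats.normaltest) and frozen here
  x20 <- c(2.3, 1.1, 4.5, 3.3, 2.2, 5.9, 0.4, 3.1, 2.8, 4.0,
           1.9, 2.5, 3.7, 6.2, 0.9, 2.0, 3.4, 2.9, 1.5, 4.8)
  h <- dagostino_pearson(x20)
  expect_equal(unname(h$statistic), 0.968743699394123, tolerance = 1e-12)
  expect_equal(h$p.value, 0.616084068639073, tolerance = 1e-12)

  e12 <- exp(seq(0, 3, length.out = 12))
  h2 <- dagostino_pearson(e12)
  expect_equal(unname(h2$statistic), 3.8158948491419875, tolerance = 1e-12)
  expect_equal(h2$p.value, 0.1483846449082528, tolerance = 1e-12)
})

test_that("normality test rejects skewed data and accepts normal data", {
  withr::with_seed(5, {
    normal_p <- replicate(40, dagostino_pearson(rnorm(500))$p.value)
    skewed_p <- replicate(20, dagostino_pearson(rexp(500))$p.value)
  })
  expect_gte(mean(normal_p > 0.05), 0.90)
  expect_true(all(skewed_p < 0.01))
})

test_that("sample-size floor and zero variance are rejected", {
  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
  expect_error(dagostino_pearson(rep(3, 20)), "zero variance")
})

test_that("the star map reproduces the conventional legend exactly", {
  expect_identical(p_stars(c(0.00005, 0.0005, 0.004, 0.04, 0.4, 1)),
                   c("****", "***", "**", "*", "ns", "ns"))
  # boundaries belong to the weaker annotation
  expect_identical(p_stars(c(1e-4, 1e-3, 1e-2, 5e-2)),
                   c("***", "**", "*", "ns"))
  expect_error(p_stars(1.2))
})

test_that("two-sample comparison matches the closed-form t", {
  # equal variance, equal n: Welch reduces to Student's t = -2, df = 8
  gc <- compare_groups(1:5, 3:7, test = "t")
  expect_equal(gc$statistic, -2)
  expect_equal(gc$p_value, 2 * stats::pt(-2, 8), tolerance = 1e-12)
  expect_equal(gc$test_used, "Welch t")
  expect_equal(gc$stars, "ns")

  gs <- compare_groups(1:5, 3:7, test = "t", var.equal = TRUE)
  expect_equal(gs$statistic, -2)
  expect_equal(gs$test_used, "Student t")
})

test_that("identical groups compare as a null result", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  gc <- compare_groups(x, x, test = "t")
  expect_equal(gc$statistic, 0)
  expect_equal(gc$p_value, 1)
  expect_equal(gc$stars, "ns")
  expect_error(compare_groups(numeric(0), x), "non-empty")
})

test_that("the normality gate routes to t or rank-sum and records it", {
  withr::with_seed(8, {
    a <- rnorm(60); b <- rnorm(60, 0.2)
    sk <- rexp(60)
  })
  g1 <- compare_groups(a, b)
  expect_equal(g1$test_used, "Welch t")
  expect_true(all(g1$normality_p > 0.05))
  g2 <- compare_groups(a, sk)
  expect_equal(g2$test_used, "Wilcoxon rank-sum")
  expect_lt(g2$normality_p[2], 0.05)
  # below the n = 8 floor the gate is skipped in favour of the rank-sum
  g3 <- compare_groups(1:5, c(2, 4, 6, 8, 10))
  expect_equal(g3$test_used, "Wilcoxon rank-sum")
  expect_true(all(is.na(g3$normality_p)))
})

test_that("the full comparison pipeline holds its type-I error near alpha", {
  withr::with_seed(17, {
    rej <- replicate(400, {
      compare_groups(rnorm(30), rnorm(30))$p_value < 0.05
    })
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("summaries are permutation-invariant and validate inputs", {
  sc <- small_scene(3)
  rec <- analyze_cells(sc$junction, sc$cells, default_config())
  grp <- rep(c("A", "B"), length.out = nrow(rec))
  s1 <- summarize_records(rec, grp)
  perm <- withr::with_seed(1, sample(nrow(rec)))
  s2 <- summarize_records(rec[perm, ], grp[perm])
  expect_equal(s1$comparisons$p_value, s2$comparisons$p_value)
  expect_equal(s1$summary$mean, s2$summary$mean)

  expect_error(summarize_records(rec, rep("A", nrow(rec))), "at least 2")
  expect_error(summarize_records(rec, grp[-1]), "one label per record")
  expect_error(summarize_records(rec, grp, metrics = "not_a_metric"),
               "unknown metric")

  # identical groups: every metric comparison is ns
  rec2 <- rbind(rec, rec)
  g2 <- rep(c("A", "B"), each = nrow(rec))
  s3 <- summarize_records(rec2, g2, test = "t",
                          metrics = c("coverage_continuous",
                                      "coverage_total", "area_um2"))
  expect_true(all(s3$comparisons$stars == "ns"))

  # holm adjustment never lowers p values
  s4 <- summarize_records(rec, grp, adjust = "holm")
  expect_true(all(s4$comparisons$p_adjusted >= s4$comparisons$p_value - 1e-15))
})
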