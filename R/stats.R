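# Group statistics for per-cell metrics: D'Agostino-Pearson omnibus
# normality screen, two-sample comparison (Welch t by default, rank-sum
# fallback for non-normal data), and the conventional star annotation.

#' D'Agostino-Pearson omnibus normality test
#'
#' K^2 = Z1(skewness)^2 + Z2(kurtosis)^2 with the standard normalizing
#' transforms (D'Agostino's skewness transform; Anscombe-Glynn kurtosis
#' transform); under normality K^2 is chi-squared with 2 degrees of freedom.
#'
#' @param x numeric sample, n >= 8 (the kurtosis transform's sample-size
#'   floor).
#' @return An object of class `htest` with `statistic` (K^2), `parameter`
#'   (df = 2), `p.value`, and the two component z-scores in `estimate`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8)
    stop("D'Agostino-Pearson needs n >= 8; skip the normality gate for ",
         "smaller samples")
  if (stats::var(x) == 0) stop("sample has zero variance")
  z1 <- .z_skewness(x)
  z2 <- .z_kurtosis(x)
  k2 <- z1^2 + z2^2
  structure(list(statistic = c("K-squared" = k2),
                 parameter = c(df = 2),
                 p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 estimate = c(z_skewness = z1, z_kurtosis = z2),
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

# D'Agostino (1970) transformed sample skewness.
.z_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
        ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
}

# Anscombe-Glynn (1983) transformed sample kurtosis.
.z_kurtosis <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
         sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  num <- 1 - 2 / (9 * a)
  den <- ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1/3)
  (num - den) / sqrt(2 / (9 * a))
}

#' Significance stars for a p value
#'
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p p value(s) in \[0, 1\].
#' @return character vector of star annotations.
#' @export
p_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 5e-2, "*", "ns"))))
}

#' Compare a per-cell metric between two groups
#'
#' Both groups are screened with [dagostino_pearson()]; if both look normal
#' (p > alpha) a two-sample t-test is used (Welch by default), otherwise a
#' Wilcoxon rank-sum test, with the choice recorded. Groups smaller than 8
#' skip the normality gate and fall back to the rank-sum test unless `test`
#' forces otherwise.
#'
#' @param a,b numeric samples.
#' @param alpha significance level for the normality gate and stars.
#' @param var.equal use Student's pooled-variance t instead of Welch.
#' @param test `"auto"` (normality-gated), `"t"`, or `"wilcox"`.
#' @param labels group labels, length 2.
#' @return An object of class `group_comparison`: labels, n, means, SDs,
#'   normality p values, `test_used`, `statistic`, `p_value`, `stars`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, var.equal = FALSE,
                           test = c("auto", "t", "wilcox"),
                           labels = c("A", "B")) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  norm_p <- c(NA_real_, NA_real_)
  if (test == "auto") {
    if (length(a) >= 8 && length(b) >= 8 &&
        stats::var(a) > 0 && stats::var(b) > 0) {
      norm_p <- c(dagostino_pearson(a)$p.value, dagostino_pearson(b)$p.value)
      test <- if (all(norm_p > alpha)) "t" else "wilcox"
    } else {
      test <- "wilcox"
    }
  }
  if (test == "t") {
    ht <- stats::t.test(a, b, var.equal = var.equal)
    used <- if (var.equal) "Student t" else "Welch t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    used <- "Wilcoxon rank-sum"
  }
  structure(list(labels = labels, n = c(length(a), length(b)),
                 mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)),
                 normality_p = norm_p, alpha = alpha, test_used = used,
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 stars = p_stars(ht$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d, mean %.4g, sd %.4g) vs %s (n=%d, mean %.4g, sd %.4g)\n",
              x$labels[1], x$n[1], x$mean[1], x$sd[1],
              x$labels[2], x$n[2], x$mean[2], x$sd[2]))
  cat(sprintf("  %s: statistic = %.4g, p = %.4g  %s\n",
              x$test_used, x$statistic, x$p_value, x$stars))
  if (!all(is.na(x$normality_p)))
    cat(sprintf("  normality p: %.3g / %.3g (alpha = %g)\n",
                x$normality_p[1], x$normality_p[2], x$alpha))
  invisible(x)
}

#' Summarize cell records across groups
#'
#' Per-metric, per-group mean/SD/n plus one [compare_groups()] result per
#' metric and group pair. Raw p values are reported by default, mirroring
#' the usual per-metric reporting; an optional Holm adjustment is available.
#'
#' @param records a `cell_records` data.frame (rows from one or more
#'   [analyze_cells()] runs, row-bound).
#' @param group character/factor vector, one label per record row.
#' @param metrics metric columns to summarize.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or `"holm"` across metrics.
#' @param ... passed to [compare_groups()] (e.g. `var.equal`, `test`).
#' @return list of class `junction_summary`: `summary` (data.frame metric x
#'   group stats) and `comparisons` (data.frame, one row per metric and
#'   group pair).
#' @export
summarize_records <- function(records, group,
                              metrics = c("coverage_continuous",
                                          "coverage_punctate",
                                          "coverage_perpendicular",
                                          "coverage_total", "area_um2",
                                          "perimeter_um", "circularity",
                                          "solidity"),
                              alpha = 0.05, adjust = c("none", "holm"),
                              ...) {
  adjust <- match.arg(adjust)
  group <- as.character(group)
  if (length(group) != nrow(records))
    stop("`group` must have one label per record row")
  levels <- unique(group)
  if (length(levels) < 2) stop("need at least 2 groups to compare")
  missing_m <- setdiff(metrics, colnames(records))
  if (length(missing_m) > 0)
    stop("unknown metric column(s): ", paste(missing_m, collapse = ", "))

  summ <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(levels, function(g) {
      v <- records[[m]][group == g]
      data.frame(metric = m, group = g, n = length(v),
                 mean = mean(v), sd = sd(v))
    }))
  }))

  pairs <- utils::combn(levels, 2, simplify = FALSE)
  comp <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(pairs, function(pr) {
      gc <- compare_groups(records[[m]][group == pr[1]],
                           records[[m]][group == pr[2]],
                           alpha = alpha, labels = pr, ...)
      data.frame(metric = m, group_a = pr[1], group_b = pr[2],
                 n_a = gc$n[1], n_b = gc$n[2],
                 mean_a = gc$mean[1], mean_b = gc$mean[2],
                 normality_p_a = gc$normality_p[1],
                 normality_p_b = gc$normality_p[2],
                 test = gc$test_used, statistic = gc$statistic,
                 p_value = gc$p_value, stars = gc$stars)
    }))
  }))
  if (adjust == "holm") {
    comp$p_adjusted <- stats::p.adjust(comp$p_value, method = "holm")
    comp$stars <- p_stars(comp$p_adjusted)
  }
  structure(list(summary = summ, comparisons = comp, alpha = alpha,
                 adjust = adjust),
            class = "junction_summary")
}

#' @export
print.junction_summary <- function(x, ...) {
  cat("<junction_summary>\n")
  print.data.frame(x$comparisons[, c("metric", "group_a", "group_b", "test",
                                     "p_value", "stars")], digits = 4)
  invisible(x)
}

#' Dot plots with mean and SD bars per metric and group
#'
#' @param x a [summarize_records()] result.
#' @param records,group the records and labels used to build `x`.
#' @param metrics metrics to plot (default: all summarized).
#' @param ... unused.
#' @export
plot.junction_summary <- function(x, records, group,
                                  metrics = unique(x$summary$metric), ...) {
  group <- as.character(group)
  old <- graphics::par(mfrow = c(ceiling(length(metrics) / 2),
                                 min(2, length(metrics))))
  on.exit(graphics::par(old))
  for (m in metrics) {
    vals <- split(records[[m]], group)
    graphics::stripchart(vals, vertical = TRUE, method = "jitter",
                         pch = 16, cex = 0.5, col = "grey40", main = m,
                         ylab = m)
    for (i in seq_along(vals)) {
      mu <- mean(vals[[i]]); s <- sd(vals[[i]])
      graphics::lines(i + c(-0.2, 0.2), c(mu, mu), lwd = 2)
      graphics::arrows(i, mu - s, i, mu + s, angle = 90, code = 3,
                       length = 0.05)
    }
  }
  invisible(x)
}
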