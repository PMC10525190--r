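# Intensity-guided cell border tracing.
#
# Between each consecutive waypoint pair the border follows the minimum-cost
# 8-connected path where the cost of entering a pixel is
# (max intensity - intensity) + eps, eps = 1e-3 * dynamic range, so bright
# junction staining attracts the path and every step has strictly positive
# cost. Cost ties are resolved by the geometrically shorter path, then by the
# path closest to the straight waypoint chord, then by a fixed neighbour
# order (E, NE, N, NW, W, SW, S, SE) - fully deterministic.

#' Trace a cell border along junction staining
#'
#' @param sheet an [unwrapped_sheet()] (or plain matrix) holding the junction
#'   channel.
#' @param waypoints a closed [waypoint_set()] in the `"sheet"` frame;
#'   coordinates are 1-based (row, col) pixel indices.
#' @param margin_px half-width of the search window around each waypoint
#'   pair's bounding box, in px. The minimum-cost search runs inside this
#'   window.
#' @param diag_penalty_frac extra cost per diagonal step, as a fraction of
#'   the image's dynamic range (default 0.15). Every minimal 8-connected
#'   path between two pixels uses the same number of diagonal steps, so the
#'   penalty leaves noise-free tracing unchanged; it keeps intensity
#'   fluctuations smaller than the penalty from deflecting the path into
#'   zigzag detours on noisy images.
#' @return An object of class `cell_border`: list with `path` (closed n x 2
#'   chain of (row, col) pixels, 8-connected, no repeats), `perimeter_px`
#'   (sqrt(2)-weighted closed chain length), `perimeter_um`, `waypoints`,
#'   and `pixel_size`.
#' @export
trace_border <- function(sheet, waypoints, margin_px = 40,
                         diag_penalty_frac = 0.15) {
  img <- if (inherits(sheet, "unwrapped_sheet")) sheet$data else sheet
  pixel_size <- if (inherits(sheet, "unwrapped_sheet")) sheet$pixel_size
                else c(1, 1)
  stopifnot(inherits(waypoints, "waypoint_set"))
  if (!waypoints$closed || nrow(waypoints$points) < 3)
    stop("cell borders need a closed waypoint set with >= 3 points")
  wp <- round(waypoints$points)
  nr <- nrow(img); nc <- ncol(img)
  bad <- wp[, 1] < 1 | wp[, 1] > nr | wp[, 2] < 1 | wp[, 2] > nc
  if (any(bad))
    stop(sprintf("waypoint (%g, %g) lies outside the %d x %d image",
                 wp[which(bad)[1], 1], wp[which(bad)[1], 2], nr, nc))

  rng <- diff(range(img))
  eps <- 1e-3 * max(rng, 1)
  tol <- 1e-9 * (rng + 1)
  mx <- max(img)
  dpen <- diag_penalty_frac * rng

  n <- nrow(wp)
  chain <- NULL
  for (k in seq_len(n)) {
    a <- wp[k, ]; b <- wp[if (k == n) 1 else k + 1, ]
    seg <- .trace_pair(img, a, b, mx, eps, tol, margin_px, dpen)
    chain <- if (is.null(chain)) seg else rbind(chain, seg[-1, , drop = FALSE])
  }
  # the final segment ends at the first waypoint: drop the duplicate closure
  if (nrow(chain) > 1 && all(chain[nrow(chain), ] == chain[1, ]))
    chain <- chain[-nrow(chain), , drop = FALSE]
  chain <- .prune_revisits(chain)

  w <- chain_step_weights(chain, closed = TRUE)
  # physical perimeter from the simplified polygon: unbiased for straight
  # digital segments (the raw sqrt(2)-chain overestimates sloped borders by
  # up to ~8%); perimeter_px keeps the exact chain arc for coverage
  keep <- simplify_chain(chain)
  sp <- chain[keep, , drop = FALSE] - 1
  spum <- sp * matrix(pixel_size, length(keep), 2, byrow = TRUE)
  dd <- spum[c(2:nrow(spum), 1), , drop = FALSE] - spum
  per_um <- sum(sqrt(dd[, 1]^2 + dd[, 2]^2))

  structure(list(path = chain, perimeter_px = sum(w), perimeter_um = per_um,
                 simplified = keep, waypoints = waypoints,
                 pixel_size = pixel_size),
            class = "cell_border")
}

.trace_pair <- function(img, a, b, mx, eps, tol, margin_px, dpen = 0) {
  r0 <- max(1, min(a[1], b[1]) - margin_px)
  r1 <- min(nrow(img), max(a[1], b[1]) + margin_px)
  c0 <- max(1, min(a[2], b[2]) - margin_px)
  c1 <- min(ncol(img), max(a[2], b[2]) + margin_px)
  win <- img[r0:r1, c0:c1, drop = FALSE]
  cost <- (mx - win) + eps
  p <- .min_cost_path_cpp(cost, a[1] - r0, a[2] - c0, b[1] - r0, b[2] - c0,
                          tol, dpen)
  p + matrix(c(r0, c0), nrow(p), 2, byrow = TRUE)
}

# Remove self-crossings from a concatenated chain. A repeated pixel splits
# the closed chain into two loops; the smaller loop (typically a few-pixel
# corner spur where consecutive segment traces overlap) is dropped so the
# border stays a simple closed chain.
.prune_revisits <- function(chain) {
  repeat {
    key <- chain[, 1] * 1e9 + chain[, 2]
    d <- duplicated(key)
    if (!any(d)) return(chain)
    j <- which(d)[1]
    i <- match(key[j], key)
    n <- nrow(chain)
    if (j - i <= n - (j - i)) {
      chain <- chain[-(i:(j - 1)), , drop = FALSE]
    } else {
      chain <- chain[i:(j - 1), , drop = FALSE]
    }
  }
}

#' @export
print.cell_border <- function(x, ...) {
  cat(sprintf("<cell_border> %d path pixels, perimeter %.1f px (%.2f um)\n",
              nrow(x$path), x$perimeter_px, x$perimeter_um))
  invisible(x)
}

#' Brute-force minimum-cost path by exhaustive enumeration
#'
#' Independent validation oracle for [trace_border()]: depth-first
#' enumeration of all simple 8-connected paths between two pixels with
#' branch-and-bound pruning, using the same cost and tie-break definition
#' (cost, then Euclidean length, then squared deviation from the chord).
#' Exponential - only usable on small grids (<= 8 x 8).
#'
#' @param img small numeric matrix.
#' @param a,b (row, col) endpoints, 1-based.
#' @param eps additive per-pixel cost offset; default matches
#'   [trace_border()].
#' @param diag_penalty extra cost per diagonal step (same definition as in
#'   the production tracer).
#' @return n x 2 matrix of the optimal path, endpoints included.
#' @export
brute_force_min_cost_path <- function(img, a, b, eps = NULL,
                                      diag_penalty = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr * nc > 64) stop("exhaustive enumeration is limited to <= 64 pixels")
  rng <- diff(range(img))
  if (is.null(eps)) eps <- 1e-3 * max(rng, 1)
  cost <- (max(img) - img) + eps
  chord <- function(r, c) {
    bx <- b[1] - a[1]; by <- b[2] - a[2]
    bn <- sqrt(bx^2 + by^2)
    if (bn == 0) return(0)
    ((r - a[1]) * by / bn - (c - a[2]) * bx / bn)^2
  }
  best <- list(key = c(Inf, Inf, Inf), path = NULL)
  visited <- matrix(FALSE, nr, nc)
  moves <- cbind(dr = c(0, -1, -1, -1, 0, 1, 1, 1),
                 dc = c(1, 1, 0, -1, -1, -1, 0, 1))
  path <- matrix(0L, nr * nc, 2)
  rec <- function(r, c, depth, kcost, klen, kdev) {
    if (kcost > best$key[1] + 1e-12) return()
    path[depth, ] <<- c(r, c)
    if (r == b[1] && c == b[2]) {
      key <- c(kcost, klen, kdev)
      if (.lex_less(key, best$key))
        best <<- list(key = key, path = path[1:depth, , drop = FALSE])
      return()
    }
    visited[r, c] <<- TRUE
    for (k in 1:8) {
      r2 <- r + moves[k, 1]; c2 <- c + moves[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || visited[r2, c2]) next
      diag <- moves[k, 1] != 0 && moves[k, 2] != 0
      step <- if (diag) sqrt(2) else 1
      rec(r2, c2, depth + 1,
          kcost + cost[r2, c2] + if (diag) diag_penalty else 0,
          klen + step, kdev + chord(r2, c2))
    }
    visited[r, c] <<- FALSE
  }
  rec(a[1], a[2], 1, 0, 0, 0)
  best$path
}

.lex_less <- function(x, y, tol = 1e-9) {
  for (i in seq_along(x)) {
    if (x[i] < y[i] - tol) return(TRUE)
    if (x[i] > y[i] + tol) return(FALSE)
  }
  FALSE
}
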