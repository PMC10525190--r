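# Small numeric helpers shared across modules.

#' Normalized cross-correlation of two images
#'
#' Pearson correlation of the flattened pixel values; 1 means the images are
#' identical up to an affine intensity transform.
#'
#' @param a,b numeric arrays of identical dimensions.
#' @return A scalar in \[-1, 1\].
#' @export
ncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) stop("ncc undefined for constant images")
  sum(a * b) / den
}

# Shoelace area of a polygon given as an n x 2 matrix of (x, y) vertices.
# The closing edge is implied. Returns the unsigned area.
shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Step weights of an 8-connected pixel chain (n x 2 matrix), closing step
# included when closed = TRUE. Diagonal steps weigh sqrt(2).
chain_step_weights <- function(path, closed = TRUE) {
  n <- nrow(path)
  idx <- if (closed) c(2:n, 1) else 2:n
  dr <- abs(path[idx, 1] - path[if (closed) 1:n else 1:(n - 1), 1])
  dc <- abs(path[idx, 2] - path[if (closed) 1:n else 1:(n - 1), 2])
  ifelse(dr + dc == 2, sqrt(2), 1)
}

# Douglas-Peucker simplification of a closed pixel chain. Returns indices of
# kept vertices (in order). With tol ~ the half-pixel digitization tube,
# digital straight segments collapse to their endpoints, so Euclidean
# lengths measured on the simplified polygon are unbiased for straight and
# polygonal borders while genuine wiggles above `tol` are preserved.
simplify_chain <- function(path, tol = 0.7) {
  n <- nrow(path)
  if (n <= 3) return(seq_len(n))
  d1 <- (path[, 1] - path[1, 1])^2 + (path[, 2] - path[1, 2])^2
  k <- which.max(d1)
  keep <- c(.dp_section(path, 1, k, tol), .dp_section(path, k, n, tol), 1)
  unique(keep[-length(keep)])
}

# iterative Douglas-Peucker on the open section [a, b]
.dp_section <- function(path, a, b, tol) {
  keep <- c(a, b)
  stack <- list(c(a, b))
  while (length(stack) > 0) {
    ab <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ab[1]; j <- ab[2]
    if (j - i < 2) next
    p <- path[i, ]; q <- path[j, ]
    v <- q - p
    L <- sqrt(sum(v^2))
    ii <- (i + 1):(j - 1)
    dev <- if (L == 0) {
      sqrt((path[ii, 1] - p[1])^2 + (path[ii, 2] - p[2])^2)
    } else {
      abs((path[ii, 1] - p[1]) * v[2] - (path[ii, 2] - p[2]) * v[1]) / L
    }
    m <- which.max(dev)
    if (dev[m] > tol) {
      k <- ii[m]
      keep <- c(keep, k)
      stack <- c(stack, list(c(i, k)), list(c(k, j)))
    }
  }
  sort(unique(keep))
}

# 1D Gaussian blur along the first dimension of a matrix, replicate padding.
blur_cols <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  nr <- nrow(m)
  padded <- rbind(m[rep(1L, half), , drop = FALSE], m,
                  m[rep(nr, half), , drop = FALSE])
  out <- stats::filter(padded, k, sides = 2)
  matrix(out[(half + 1):(half + nr), ], nrow = nr)
}

# Separable isotropic Gaussian blur of a 3D array, sigma in voxels per axis.
blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = d[ax])
    m <- blur_cols(m, s)
    a <- array(m, dim = d[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

# Gaussian blur of a 2D matrix (separable), sigma in pixels per axis.
blur2d <- function(m, sigma_px) {
  if (length(sigma_px) == 1) sigma_px <- rep(sigma_px, 2)
  m <- blur_cols(m, sigma_px[1])
  t(blur_cols(t(m), sigma_px[2]))
}
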