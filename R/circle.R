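# Lumen circle fitting in the cross-section plane.
#
# Waypoints arrive as (z, y) pixel indices on a cross-section; they are
# converted to um (z_um = (z - 1) * dz, y_um = (y - 1) * dy) before fitting
# because confocal stacks are anisotropic (dz != dy in general).
#
# Angle convention: theta measured from the +y direction, increasing towards
# +z, i.e. a surface point at angle theta sits at
#   z = cz + rho * sin(theta),  y = cy + rho * cos(theta).

#' Fit the lumen circle to cross-section waypoints
#'
#' Algebraic least-squares circle (Kasa fit) followed by a Gauss-Newton
#' geometric refinement minimizing the RMS point-to-circle distance. The
#' angular span covered by the waypoints is inferred from the largest angular
#' gap and snapped to a half (pi) or full (2*pi) cylinder when within 15
#' degrees.
#'
#' @param waypoints a [waypoint_set()] in the `"cross_section"` frame with at
#'   least 3 non-collinear points.
#' @param voxel_size (dz, dy, dx) in um; only dz and dy are used.
#' @return An object of class `circle_fit` with elements `center` (cz, cy in
#'   um), `radius` (um), `span` and `theta0` (radians), `residual` (RMS
#'   point-to-circle distance, um), `n_points`, and `warnings`.
#' @export
fit_circle <- function(waypoints, voxel_size) {
  stopifnot(inherits(waypoints, "waypoint_set"))
  if (waypoints$frame != "cross_section")
    stop("circle fitting expects waypoints in the cross_section frame")
  pts <- waypoints$points
  if (nrow(pts) < 3) stop("need at least 3 waypoints to fit a circle")
  voxel_size <- as.numeric(voxel_size)
  zu <- (pts[, 1] - 1) * voxel_size[1]
  yu <- (pts[, 2] - 1) * voxel_size[2]

  k <- .kasa_circle(zu, yu)
  g <- .refine_circle(zu, yu, k$center, k$radius)

  ang <- atan2(zu - g$center[1], yu - g$center[2]) %% (2 * pi)
  sp <- .infer_span(ang)
  warn <- character(0)
  if (sp$span < pi / 6) warn <- c(warn, sprintf(
    "waypoints cover only %.1f degrees of arc; fit may be poorly constrained",
    sp$span * 180 / pi))

  structure(list(center = g$center, radius = g$radius,
                 span = sp$span, theta0 = sp$theta0,
                 residual = g$residual,
                 algebraic = list(center = k$center, radius = k$radius),
                 n_points = nrow(pts), warnings = warn),
            class = "circle_fit")
}

# Kasa algebraic fit: minimize sum((x^2+y^2) - (D x + E y + F))^2.
.kasa_circle <- function(x, y) {
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3)
    stop("degenerate circle fit: waypoints are collinear")
  coef <- qr.coef(qrA, b)
  cx <- coef[1] / 2; cy <- coef[2] / 2
  r2 <- coef[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate circle fit: waypoints are collinear")
  list(center = unname(c(cx, cy)), radius = unname(sqrt(r2)))
}

# Gauss-Newton on residual_i = |p_i - c| - r.
.refine_circle <- function(x, y, center, radius, max_iter = 50,
                           tol = 1e-12) {
  par <- c(center, radius)
  for (it in seq_len(max_iter)) {
    dx <- x - par[1]; dy <- y - par[2]
    d <- sqrt(dx^2 + dy^2)
    d[d == 0] <- .Machine$double.eps
    res <- d - par[3]
    J <- cbind(-dx / d, -dy / d, -1)
    step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    par <- par - as.numeric(step)
    if (max(abs(step)) < tol * max(1, abs(par[3]))) break
  }
  dx <- x - par[1]; dy <- y - par[2]
  res <- sqrt(dx^2 + dy^2) - par[3]
  list(center = par[1:2], radius = par[3],
       residual = sqrt(mean(res^2)))
}

# Angular span from the largest gap between sorted waypoint angles, snapped
# to pi or 2*pi within 15 degrees. theta0 is the start of the covered arc
# (snapped to the nearest multiple of pi/2 when the span snaps).
.infer_span <- function(ang) {
  snap <- pi / 12  # 15 degrees
  a <- sort(ang)
  gaps <- diff(c(a, a[1] + 2 * pi))
  gmax <- max(gaps)
  k <- which.max(gaps)
  span_raw <- 2 * pi - gmax
  theta0_raw <- if (k == length(a)) a[1] else a[k + 1]
  if (gmax <= snap) {
    list(span = 2 * pi, theta0 = 0)
  } else if (abs(span_raw - pi) <= snap) {
    list(span = pi, theta0 = (round(theta0_raw / (pi / 2)) * (pi / 2)) %% (2 * pi))
  } else {
    list(span = span_raw, theta0 = theta0_raw)
  }
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (z, y) = (%.3f, %.3f) um, radius %.3f um\n",
              x$center[1], x$center[2], x$radius))
  cat(sprintf("  span %.1f deg from theta0 %.1f deg, RMS residual %.4g um (n = %d)\n",
              x$span * 180 / pi, x$theta0 * 180 / pi, x$residual, x$n_points))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
coef.circle_fit <- function(object, ...) {
  c(center_z = object$center[1], center_y = object$center[2],
    radius = object$radius)
}

#' @export
residuals.circle_fit <- function(object, ...) object$residual

#' Point on the fitted circle at a given angle
#'
#' @param object a `circle_fit`.
#' @param theta angles in radians (from +y towards +z).
#' @param ... unused.
#' @return An n x 2 matrix of (z, y) positions in um.
#' @export
predict.circle_fit <- function(object, theta, ...) {
  cbind(z = object$center[1] + object$radius * sin(theta),
        y = object$center[2] + object$radius * cos(theta))
}

#' Brute-force grid-search circle fit
#'
#' Independent validation oracle: exhaustively searches a (cz, cy, r) grid at
#' fixed resolution for the circle minimizing the RMS point-to-circle
#' distance. Intended for testing [fit_circle()] on small point sets, not
#' for production use.
#'
#' @param z,y point coordinates in um.
#' @param resolution grid step in um (default 0.05).
#' @param pad half-width of the search box around a coarse moment-based
#'   initial guess, in um.
#' @return list with `center`, `radius`, `residual`.
#' @export
grid_search_circle <- function(z, y, resolution = 0.05, pad = 3) {
  cz0 <- mean(z); cy0 <- mean(y)
  r0 <- mean(sqrt((z - cz0)^2 + (y - cy0)^2))
  czs <- seq(cz0 - pad, cz0 + pad, by = resolution)
  cys <- seq(cy0 - pad, cy0 + pad, by = resolution)
  rs <- seq(max(resolution, r0 - pad), r0 + pad, by = resolution)
  best <- list(residual = Inf)
  for (cz in czs) {
    dz2 <- (z - cz)^2
    for (cy in cys) {
      d <- sqrt(dz2 + (y - cy)^2)
      # optimal RMS over r for fixed center is at r = mean(d); evaluate the
      # nearest grid radii only
      rg <- rs[order(abs(rs - mean(d)))[1:2]]
      for (r in rg) {
        rms <- sqrt(mean((d - r)^2))
        if (rms < best$residual)
          best <- list(center = c(cz, cy), radius = r, residual = rms)
      }
    }
  }
  best
}
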