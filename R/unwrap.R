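# Cylindrical surface unwrapping.
#
# Each sheet row i (1-based) corresponds to arc position s = (i - 1) * ds and
# angle theta = theta0 + s / radius; each column j to axial index j of the
# volume. Intensity at a surface point is sampled along the radial ray
# through a band centered on the fitted radius and combined by max or mean
# projection. Bilinear interpolation in the (z, y) plane; samples falling
# outside the volume contribute 0 and their fraction is reported.

#' Extract a (z, y) cross-section from a volume
#'
#' @param volume a [voxel_volume()].
#' @param axial_index 1-based index along x.
#' @return An object of class `cross_section`: list with `data` (nz x ny
#'   matrix, raw values) and `pixel_size` (dz, dy) for aspect-true display.
#' @export
extract_cross_section <- function(volume, axial_index) {
  stopifnot(inherits(volume, "voxel_volume"))
  nx <- dim(volume$data)[3]
  if (length(axial_index) != 1 || axial_index < 1 || axial_index > nx ||
      axial_index != round(axial_index))
    stop("axial_index must be an integer in [1, ", nx, "]")
  structure(list(data = volume$data[, , axial_index],
                 pixel_size = volume$voxel_size[1:2],
                 axial_index = axial_index),
            class = "cross_section")
}

#' @export
plot.cross_section <- function(x, ...) {
  d <- dim(x$data)
  graphics::image(x = (seq_len(d[2]) - 1) * x$pixel_size[2],
                  y = (seq_len(d[1]) - 1) * x$pixel_size[1],
                  z = t(x$data), xlab = "y (um)", ylab = "z (um)",
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Unwrap a vessel volume into a flat sheet
#'
#' @param volume a [voxel_volume()].
#' @param circle a [fit_circle()] result (or compatible list) in the same
#'   cross-section frame.
#' @param radial_band width of the sampled radial band in um (default 6,
#'   about one endothelial monolayer thickness).
#' @param ds circumferential pixel size of the sheet in um; default
#'   `min(dz, dy) / 2`.
#' @param projection how to combine samples along each radial ray.
#' @param span,theta0 optional overrides of the fitted angular span/origin.
#' @param max_oob_fraction error if more than this fraction of samples falls
#'   outside the volume (default 0.25).
#' @return An [unwrapped_sheet()]; provenance records the circle, band,
#'   sampling parameters and out-of-bounds fraction.
#' @export
unwrap_volume <- function(volume, circle, radial_band = 6, ds = NULL,
                          projection = c("max", "mean"),
                          span = NULL, theta0 = NULL,
                          max_oob_fraction = 0.25) {
  stopifnot(inherits(volume, "voxel_volume"))
  projection <- match.arg(projection)
  if (radial_band <= 0) stop("radial_band must be > 0")
  vs <- volume$voxel_size
  if (is.null(ds)) ds <- min(vs[1], vs[2]) / 2
  span <- span %||% circle$span
  theta0 <- theta0 %||% circle$theta0
  r <- circle$radius
  if (is.null(r) || r <= 0) stop("circle radius must be positive")

  n_rows <- max(1L, round(span * r / ds))
  theta <- theta0 + (seq_len(n_rows) - 1) * ds / r

  rstep <- min(vs[1], vs[2]) / 2
  m <- max(1L, floor(radial_band / rstep)) + 1L
  rho <- seq(r - radial_band / 2, r + radial_band / 2, length.out = m)

  # sample positions in the (z, y) plane are the same for every axial column
  zz <- outer(sin(theta), rho) + circle$center[1]   # n_rows x m, um
  yy <- outer(cos(theta), rho) + circle$center[2]
  gi <- .bilinear_plan(zz / vs[1], yy / vs[2],
                       dim(volume$data)[1], dim(volume$data)[2])

  nx <- dim(volume$data)[3]
  sheet <- matrix(0, n_rows, nx)
  for (j in seq_len(nx)) {
    plane <- volume$data[, , j]
    v <- gi$w1 * plane[gi$i1] + gi$w2 * plane[gi$i2] +
         gi$w3 * plane[gi$i3] + gi$w4 * plane[gi$i4]
    dim(v) <- c(n_rows, m)
    sheet[, j] <- if (projection == "max") do.call(pmax, asplit(v, 2))
                  else rowMeans(v)
  }

  oob <- gi$oob_fraction
  if (oob > max_oob_fraction)
    stop(sprintf("%.1f%% of surface samples fall outside the volume; ",
                 100 * oob),
         "the fitted circle does not match this stack")

  unwrapped_sheet(sheet, pixel_size = c(ds, vs[3]),
                  provenance = list(
                    circle = list(center = circle$center, radius = r,
                                  span = span, theta0 = theta0,
                                  residual = circle$residual %||% NA),
                    radial_band = radial_band, ds = ds, rstep = rstep,
                    n_radial = m, projection = projection,
                    oob_fraction = oob))
}

# Precompute bilinear gather indices/weights for fractional (row, col)
# positions (0-based, pixel-center) on an nr x nc grid. Out-of-range samples
# get zero weight; their fraction is reported.
.bilinear_plan <- function(pr, pc, nr, nc) {
  pr <- as.numeric(pr); pc <- as.numeric(pc)
  inside <- pr >= 0 & pr <= nr - 1 & pc >= 0 & pc <= nc - 1
  r0 <- floor(pr); c0 <- floor(pc)
  fr <- pr - r0; fc <- pc - c0
  # clamp the upper neighbour at the last index (weight continuous at edges)
  r1 <- pmin(r0 + 1, nr - 1); c1 <- pmin(c0 + 1, nc - 1)
  r0c <- pmin(pmax(r0, 0), nr - 1); c0c <- pmin(pmax(c0, 0), nc - 1)
  w1 <- (1 - fr) * (1 - fc); w2 <- fr * (1 - fc)
  w3 <- (1 - fr) * fc;       w4 <- fr * fc
  w1[!inside] <- 0; w2[!inside] <- 0; w3[!inside] <- 0; w4[!inside] <- 0
  lin <- function(r, c) r + c * nr + 1
  list(i1 = lin(r0c, c0c), i2 = lin(r1, c0c),
       i3 = lin(r0c, c1),  i4 = lin(r1, c1),
       w1 = w1, w2 = w2, w3 = w3, w4 = w4,
       oob_fraction = mean(!inside))
}

#' Unwrap a truncated (half) stack
#'
#' Stacks truncated near the fitted center plane (the half-cylinder workflow
#' used when full stacks exceed memory) are unwrapped over a half span
#' (`span = pi`). With the package's angle convention the lower half
#' (z <= center) covers theta in \[pi, 2*pi\] and the upper half theta in
#' \[0, pi\]; the resulting rows match the corresponding rows of the
#' full-span sheet.
#'
#' @param volume the truncated [voxel_volume()].
#' @param circle the circle fitted on the full cross-section frame.
#' @param half which half the volume retains, relative to the circle center.
#' @param ... passed to [unwrap_volume()].
#' @return An [unwrapped_sheet()] with `span = pi`.
#' @export
unwrap_halfstack <- function(volume, circle, half = c("lower", "upper"),
                             ds = NULL, ...) {
  half <- match.arg(half)
  vs <- volume$voxel_size
  if (is.null(ds)) ds <- min(vs[1], vs[2]) / 2
  # snap the half's starting angle onto the full-span row grid so overlap
  # rows match the full unwrap row-for-row
  theta0 <- if (half == "lower") pi else 0
  theta0 <- round(theta0 * circle$radius / ds) * ds / circle$radius
  unwrap_volume(volume, circle, span = pi, theta0 = theta0, ds = ds, ...)
}
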