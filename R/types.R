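# Core containers. Conventions used throughout:
#  * volumes are indexed (z, y, x); sheets are indexed (row = arc position s,
#    col = axial position x);
#  * R indices are 1-based; the physical position of index i along an axis
#    with spacing d is (i - 1) * d (pixel-center convention), so index 1 sits
#    at 0 um;
#  * all physical quantities are in micrometres.

#' Construct a voxel volume
#'
#' A single-channel 3D intensity stack with physical voxel sizes.
#'
#' @param data 3D numeric array indexed (z, y, x), nonnegative.
#' @param voxel_size numeric length-3, voxel spacing (dz, dy, dx) in um.
#' @param channel_name free-text channel label (e.g. "ZO-1").
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_size, channel_name = "") {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3D array indexed (z, y, x)")
  if (any(dim(data) < 1)) stop("all three dimensions must be >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values (dz, dy, dx) in um")
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  structure(list(data = data, voxel_size = voxel_size,
                 channel_name = as.character(channel_name)[1]),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %s  (z,y,x) = %d x %d x %d, voxel %.3g x %.3g x %.3g um\n",
              if (nzchar(x$channel_name)) x$channel_name else "(unnamed)",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Construct an ordered waypoint set
#'
#' Ordered 2D guide points in a named coordinate frame. Frame
#' `"cross_section"` means (z, y) pixel indices on a cross-section at fixed
#' x; frame `"sheet"` means (row, col) pixel indices on an unwrapped sheet.
#' Consecutive duplicate points are collapsed.
#'
#' @param points n x 2 numeric matrix of coordinates (1-based pixel indices).
#' @param frame `"cross_section"` or `"sheet"`.
#' @param closed logical; closed sets (circle fits, cell borders) need at
#'   least 3 points.
#' @return An object of class `waypoint_set`.
#' @export
waypoint_set <- function(points, frame = c("cross_section", "sheet"),
                         closed = FALSE) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("waypoints must be an n x 2 matrix")
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("waypoint coordinates must be finite")
  if (nrow(points) > 1) {
    dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
    points <- points[!dup, , drop = FALSE]
  }
  if (closed && nrow(points) >= 2 &&
      all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (closed && nrow(points) < 3)
    stop("a closed waypoint set needs at least 3 distinct points")
  structure(list(points = points, frame = frame, closed = closed),
            class = "waypoint_set")
}

#' @export
print.waypoint_set <- function(x, ...) {
  cat(sprintf("<waypoint_set> %d points, frame = %s, %s\n",
              nrow(x$points), x$frame, if (x$closed) "closed" else "open"))
  invisible(x)
}

#' Construct an unwrapped sheet
#'
#' The flattened vessel surface: rows index circumferential arc position s
#' (increasing angle), columns index axial position x.
#'
#' @param data 2D numeric matrix, nonnegative.
#' @param pixel_size numeric length-2 (ds, dx) in um.
#' @param provenance list recording how the sheet was produced (fitted
#'   circle, radial band, sampling step, projection, ...).
#' @return An object of class `unwrapped_sheet`.
#' @export
unwrapped_sheet <- function(data, pixel_size, provenance = list()) {
  if (!is.matrix(data)) stop("`data` must be a matrix (rows = arc, cols = axial)")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) != 2 || any(pixel_size <= 0))
    stop("`pixel_size` must be two positive values (ds, dx) in um")
  if (any(data < 0, na.rm = TRUE)) stop("intensities must be nonnegative")
  structure(list(data = data, pixel_size = pixel_size,
                 provenance = provenance),
            class = "unwrapped_sheet")
}

#' @export
print.unwrapped_sheet <- function(x, ...) {
  cat(sprintf("<unwrapped_sheet> %d x %d px, pixel %.3g x %.3g um\n",
              nrow(x$data), ncol(x$data), x$pixel_size[1], x$pixel_size[2]))
  if (!is.null(x$provenance$projection))
    cat(sprintf("  projection = %s, radial band = %.3g um, oob fraction = %.3g\n",
                x$provenance$projection,
                x$provenance$radial_band %||% NA,
                x$provenance$oob_fraction %||% NA))
  invisible(x)
}

#' Display an unwrapped sheet
#'
#' @param x an `unwrapped_sheet`.
#' @param ... passed to [graphics::image()].
#' @export
plot.unwrapped_sheet <- function(x, ...) {
  d <- dim(x$data)
  graphics::image(x = (seq_len(d[2]) - 1) * x$pixel_size[2],
                  y = (seq_len(d[1]) - 1) * x$pixel_size[1],
                  z = t(x$data),
                  xlab = "axial position (um)", ylab = "arc position (um)",
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
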