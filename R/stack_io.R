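# File I/O: TIFF volumes and sheets, JSON sidecars, waypoint files.
# All format concerns live here; the math modules only see the containers.

#' Load an image volume from TIFF
#'
#' Reads a multi-page TIFF, or a directory of equally sized single-plane
#' TIFFs stacked in lexicographic filename order, into a [voxel_volume()].
#' Integer pixel data are preserved as integers.
#'
#' @param path a multi-page TIFF file or a directory of single-plane TIFFs.
#' @param voxel_size voxel spacing (dz, dy, dx) in um.
#' @param channel_name channel label stored with the volume.
#' @return A `voxel_volume` of shape (planes, height, width).
#' @export
load_volume <- function(path, voxel_size, channel_name = "") {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) stop("no TIFF planes found in directory: ", path)
    planes <- lapply(files, function(f) .read_plane(f))
    dims <- vapply(planes, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
      stop("plane size mismatch at ", basename(files[bad]),
           sprintf(": %d x %d, expected %d x %d",
                   dims[1, bad], dims[2, bad], dims[1, 1], dims[2, 1]))
    }
  } else {
    raw <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    planes <- lapply(raw, .drop_channel)
  }
  nz <- length(planes)
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  data <- array(0, dim = c(nz, ny, nx))
  for (k in seq_len(nz)) data[k, , ] <- planes[[k]]
  voxel_volume(data, voxel_size, channel_name)
}

.read_plane <- function(f) {
  .drop_channel(tiff::readTIFF(f, as.is = TRUE))
}

# Collapse an RGB(A) plane to its first channel; junction stains are
# single-channel, extra channels only arise from display exports.
.drop_channel <- function(m) {
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Save an unwrapped sheet as TIFF + JSON sidecar
#'
#' Integer-valued data in \[0, 65535\] are written as 16-bit TIFF and
#' round-trip bit-exactly; other data are written as 32-bit float with a
#' recorded intensity scale. The sidecar (`<path>.json`) carries pixel sizes
#' and the full provenance of the unwrap.
#'
#' @param sheet an [unwrapped_sheet()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
save_sheet <- function(sheet, path) {
  stopifnot(inherits(sheet, "unwrapped_sheet"))
  d <- sheet$data
  integerish <- all(d == round(d)) && max(d) <= 65535
  if (integerish) {
    ok <- try(tiff::writeTIFF(d / 65535, path, bits.per.sample = 16L),
              silent = TRUE)
    scale <- 65535
    dtype <- "uint16"
  } else {
    scale <- max(d, 1)
    ok <- try(tiff::writeTIFF(d / scale, path, bits.per.sample = 32L),
              silent = TRUE)
    dtype <- "float32"
  }
  if (inherits(ok, "try-error")) stop("cannot write sheet to ", path)
  meta <- list(pixel_size_um = sheet$pixel_size,
               dtype = dtype, scale = scale,
               provenance = sheet$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load an unwrapped sheet saved by [save_sheet()]
#'
#' @param path the TIFF path.
#' @param pixel_size optional (ds, dx) in um, required when the JSON sidecar
#'   is missing.
#' @return An `unwrapped_sheet`.
#' @export
load_sheet <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  dtype <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    pixel_size <- as.numeric(meta$pixel_size_um)
    scale <- meta$scale %||% 65535
    dtype <- meta$dtype %||% "uint16"
    prov <- meta$provenance %||% list()
  } else {
    if (is.null(pixel_size))
      stop("sidecar ", basename(sidecar), " not found; pass `pixel_size` ",
           "(ds, dx in um) explicitly")
    scale <- 65535
    prov <- list()
  }
  if (identical(dtype, "float32")) {
    # float samples: read the raw stored values and undo the intensity scale
    d <- .drop_channel(tiff::readTIFF(path)) * scale
  } else {
    d <- .drop_channel(tiff::readTIFF(path, as.is = TRUE))
    if (!is.integer(d)) d <- d * scale  # no sidecar and float samples
  }
  storage.mode(d) <- "double"
  unwrapped_sheet(d, pixel_size, if (is.list(prov)) prov else list())
}

#' Load waypoints from JSON or two-column text
#'
#' JSON files carry `points` (n x 2), `frame` and `closed`; plain-text files
#' hold two whitespace- or tab-separated columns and take frame/closed from
#' the arguments. Consecutive duplicate points are collapsed.
#'
#' @param path waypoint file.
#' @param frame coordinate frame, used for text files or to override JSON.
#' @param closed logical, used for text files or to override JSON.
#' @return A [waypoint_set()].
#' @export
load_waypoints <- function(path, frame = NULL, closed = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^\\s*[{\\[]", first)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- j$points
    if (is.null(pts)) stop("JSON waypoint file must contain `points`")
    pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2)
    frame <- frame %||% (j$frame %||% "sheet")
    closed <- closed %||% (j$closed %||% FALSE)
  } else {
    tab <- utils::read.table(path, header = FALSE)
    if (ncol(tab) < 2) stop("text waypoint file must have two columns")
    pts <- as.matrix(tab[, 1:2])
    frame <- frame %||% "sheet"
    closed <- closed %||% FALSE
  }
  waypoint_set(pts, frame = frame, closed = closed)
}

#' Save a waypoint set to JSON
#'
#' @param ws a [waypoint_set()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_waypoints <- function(ws, path) {
  stopifnot(inherits(ws, "waypoint_set"))
  jsonlite::write_json(list(points = unname(ws$points), frame = ws$frame,
                            closed = ws$closed),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
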