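# Junction isolation, segmentation, phenotype classification, coverage and
# cell morphology.
#
# Phenotype rule (path length L in px along the border, thickness
# T = segment pixel area / L, ratio rho = T / L):
#   L > continuous_min_px (default 15)  -> continuous
#   else rho > ratio_cut (default 1.2)  -> perpendicular
#   else                                -> punctate
# Boundary conventions: L exactly 15 is NOT continuous; rho exactly 1.2 is
# punctate (the strict inequalities own the boundaries).

#' Classifier configuration
#'
#' @param intensity_threshold per-image junction isolation threshold (same
#'   units as the image); a per-dataset constant chosen by the analyst, see
#'   [otsu_threshold()] for a starting point.
#' @param continuous_min_px minimum border path length (px, exclusive) for a
#'   continuous junction.
#' @param ratio_cut thickness-to-path-length ratio (exclusive) above which a
#'   short junction is perpendicular rather than punctate.
#' @param corridor_halfwidth_px half-width (px) of the corridor around the
#'   traced border within which junction pixels are attributed to the cell.
#' @param trace_margin_px search window margin for [trace_border()].
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(intensity_threshold,
                              continuous_min_px = 15,
                              ratio_cut = 1.2,
                              corridor_halfwidth_px = 5,
                              trace_margin_px = 40) {
  stopifnot(continuous_min_px > 0, ratio_cut > 0, corridor_halfwidth_px >= 1)
  structure(list(intensity_threshold = intensity_threshold,
                 continuous_min_px = continuous_min_px,
                 ratio_cut = ratio_cut,
                 corridor_halfwidth_px = corridor_halfwidth_px,
                 trace_margin_px = trace_margin_px),
            class = "classifier_config")
}

#' Threshold-isolate junction signal
#'
#' @param sheet an [unwrapped_sheet()] or matrix.
#' @param threshold scalar; the mask is `image >= threshold`.
#' @return logical matrix.
#' @export
isolate_junctions <- function(sheet, threshold) {
  img <- if (inherits(sheet, "unwrapped_sheet")) sheet$data else sheet
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  img >= threshold
}

#' Otsu starting threshold
#'
#' Convenience helper suggesting a threshold; never applied silently - the
#' analysis threshold is always an explicit [classifier_config()] entry.
#'
#' @param sheet an [unwrapped_sheet()] or matrix.
#' @return scalar threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(sheet) {
  img <- if (inherits(sheet, "unwrapped_sheet")) sheet$data else sheet
  mx <- max(img)
  if (mx == 0) return(0)
  EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1)) * mx
}

#' Extract junction segments along a cell border
#'
#' Junction-mask pixels within a corridor around the traced border are
#' grouped into 8-connected components; each component is projected onto the
#' border polyline (continuous arc-length projection, so staining oriented
#' across the border covers only a point-like run whatever the border's
#' orientation on the pixel grid) and becomes one segment with path length L
#' (covered border run + 1 px, capped at the perimeter), mean thickness
#' T = pixel area / L, and ratio rho = T / L. Components projecting to a
#' run of length 0 (a single arc position) are discarded.
#'
#' @param border a [trace_border()] result.
#' @param mask logical junction mask from [isolate_junctions()].
#' @param config a [classifier_config()].
#' @return data.frame of class `junction_segments`: one row per segment with
#'   columns `n_pixels`, `run_start` and `run_len` (arc coordinates along
#'   the border, px), `path_length_px`, `thickness_px`, `ratio`,
#'   `phenotype`.
#' @export
extract_segments <- function(border, mask, config) {
  stopifnot(inherits(border, "cell_border"))
  path <- border$path
  hw <- config$corridor_halfwidth_px
  nr <- nrow(mask); nc <- ncol(mask)
  perim <- border$perimeter_px

  # corridor computed in the border's bounding window only
  r0 <- max(1, min(path[, 1]) - hw); r1 <- min(nr, max(path[, 1]) + hw)
  c0 <- max(1, min(path[, 2]) - hw); c1 <- min(nc, max(path[, 2]) + hw)
  wr <- r1 - r0 + 1; wc <- c1 - c0 + 1
  pm <- matrix(FALSE, wr, wc)
  pm[cbind(path[, 1] - r0 + 1, path[, 2] - c0 + 1)] <- TRUE
  brush <- EBImage::makeBrush(2L * as.integer(hw) + 1L, shape = "disc")
  corridor <- EBImage::dilate(pm, brush) > 0
  cand <- corridor & mask[r0:r1, c0:c1, drop = FALSE]

  empty <- data.frame(n_pixels = integer(0), run_start = numeric(0),
                      run_len = numeric(0),
                      path_length_px = numeric(0), thickness_px = numeric(0),
                      ratio = numeric(0), phenotype = character(0))
  class(empty) <- c("junction_segments", "data.frame")
  if (!any(cand)) return(empty)

  lab <- .label8_cpp(cand)
  nlab <- max(lab)
  idx <- which(cand, arr.ind = TRUE)
  labs <- lab[cbind(idx[, 1], idx[, 2])]
  proj <- .project_polyline_cpp(idx[, 1] + r0 - 1L, idx[, 2] + c0 - 1L,
                                as.integer(path[, 1]), as.integer(path[, 2]))

  rows <- vector("list", nlab)
  for (g in seq_len(nlab)) {
    s <- sort(unique(proj[labs == g]))
    npx <- sum(labs == g)
    if (length(s) < 2) next   # run length 0
    # minimal cyclic arc interval covering the projections
    gaps <- diff(c(s, s[1] + perim))
    k <- which.max(gaps)
    run_len <- perim - gaps[k]
    if (run_len <= 0) next
    rs <- if (k == length(s)) s[1] else s[k + 1]
    L <- min(run_len + 1, perim)
    rows[[g]] <- data.frame(n_pixels = npx, run_start = rs,
                            run_len = run_len, path_length_px = L,
                            thickness_px = npx / L, ratio = (npx / L) / L,
                            phenotype = NA_character_)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$phenotype <- classify_segment(out$path_length_px, out$ratio, config)
  class(out) <- c("junction_segments", "data.frame")
  out
}

# Assign each border path pixel to at most one segment's phenotype (longest
# path length wins on overlap). Returns a character vector along the path
# ("" = uncovered). A pixel at arc position a belongs to a run starting at
# rs with length len when (a - rs) mod perimeter is within [-0.5, len + 0.5]
# (the half-pixel slack mirrors the +1 px run-length convention).
.segment_ownership <- function(border, segments) {
  np <- nrow(border$path)
  own <- character(np)
  if (nrow(segments) == 0) return(own)
  w <- chain_step_weights(border$path, closed = TRUE)
  a <- c(0, cumsum(w))[1:np]              # arc position of each path pixel
  perim <- border$perimeter_px
  ord <- order(-segments$path_length_px, seq_len(nrow(segments)))
  for (s in ord) {
    d <- (a - segments$run_start[s] + 0.5) %% perim
    ii <- which(d <= segments$run_len[s] + 1 & own == "")
    own[ii] <- segments$phenotype[s]
  }
  own
}

#' Classify junction segments
#'
#' @param L path length(s) in px.
#' @param ratio thickness-to-path-length ratio(s).
#' @param config a [classifier_config()].
#' @return character vector in `{"continuous", "punctate", "perpendicular"}`.
#' @export
classify_segment <- function(L, ratio, config = classifier_config(NA)) {
  stopifnot(all(L > 0))
  ifelse(L > config$continuous_min_px, "continuous",
         ifelse(ratio > config$ratio_cut, "perpendicular", "punctate"))
}

#' Junction coverage of a cell border
#'
#' Each border pixel carries an arc share (mean of its two incident step
#' weights) and is owned by at most one segment (longest path length wins on
#' overlap), so the three phenotype coverages sum exactly to the total and
#' the total never exceeds 1.
#'
#' @param border a [trace_border()] result.
#' @param segments a [extract_segments()] result for this border.
#' @return named numeric: `coverage_continuous`, `coverage_punctate`,
#'   `coverage_perpendicular`, `coverage_total` (fractions of perimeter).
#' @export
junction_coverage <- function(border, segments) {
  np <- nrow(border$path)
  if (border$perimeter_px <= 0) stop("border has zero perimeter")
  w <- chain_step_weights(border$path, closed = TRUE)
  share <- (w + c(w[np], w[-np])) / 2      # share[i] = (w[i-1] + w[i]) / 2
  own <- .segment_ownership(border, segments)
  tot <- border$perimeter_px
  cov <- function(ph) sum(share[own == ph]) / tot
  out <- c(coverage_continuous = cov("continuous"),
           coverage_punctate = cov("punctate"),
           coverage_perpendicular = cov("perpendicular"))
  c(out, coverage_total = sum(out))
}

#' Cell morphology from a traced border
#'
#' Area is the polygon (shoelace) area of the closed border chain; perimeter
#' is the Euclidean length of the Douglas-Peucker-simplified border polygon
#' (the raw 8-connected chain length overestimates sloped borders by up to
#' ~8%, which would bias circularity low), both in physical units.
#' Circularity is 4*pi*area/perimeter^2 (1 for a disk; digitization can push
#' it slightly above 1) and solidity is area / convex-hull area.
#'
#' @param border a [trace_border()] result (must be a simple closed chain).
#' @param pixel_size optional (ds, dx) um override; defaults to the border's.
#' @return named numeric: `area_um2`, `perimeter_um`, `circularity`,
#'   `solidity`.
#' @export
cell_morphology <- function(border, pixel_size = NULL) {
  stopifnot(inherits(border, "cell_border"))
  pixel_size <- pixel_size %||% border$pixel_size
  path <- border$path
  key <- path[, 1] * 1e9 + path[, 2]
  if (anyDuplicated(key)) {
    j <- which(duplicated(key))[1]
    stop(sprintf("self-intersecting border: pixel (%d, %d) visited twice",
                 path[j, 1], path[j, 2]))
  }
  pum <- cbind((path[, 1] - 1) * pixel_size[1],
               (path[, 2] - 1) * pixel_size[2])
  area <- shoelace_area(pum)
  keep <- simplify_chain(path)
  sp <- pum[keep, , drop = FALSE]
  d <- sp[c(2:nrow(sp), 1), , drop = FALSE] - sp
  per <- sum(sqrt(d[, 1]^2 + d[, 2]^2))
  hull <- grDevices::chull(pum)
  hull_area <- shoelace_area(pum[hull, , drop = FALSE])
  if (area <= 0 || per <= 0) stop("degenerate border: zero area or perimeter")
  c(area_um2 = area, perimeter_um = per,
    circularity = 4 * pi * area / per^2,
    solidity = area / hull_area)
}

#' Analyze all waypointed cells on a sheet
#'
#' Runs trace -> isolate -> segment -> classify -> coverage -> morphology for
#' each cell and returns one record per cell. Deterministic given inputs and
#' configuration.
#'
#' @param sheet junction-channel [unwrapped_sheet()].
#' @param cells list of closed `"sheet"`-frame [waypoint_set()]s, one per
#'   cell.
#' @param config a [classifier_config()] with the isolation threshold set.
#' @param channel_name recorded in the output.
#' @return data.frame of class `cell_records`: columns `cell_id`, `area_um2`,
#'   `perimeter_um`, `circularity`, `solidity`, `coverage_continuous`,
#'   `coverage_punctate`, `coverage_perpendicular`, `coverage_total`,
#'   `n_segments`, `channel_name`.
#' @export
analyze_cells <- function(sheet, cells, config, channel_name = "") {
  stopifnot(inherits(config, "classifier_config"), length(cells) >= 1)
  if (!is.numeric(config$intensity_threshold) ||
      is.na(config$intensity_threshold))
    stop("config$intensity_threshold must be set for analysis")
  mask <- isolate_junctions(sheet, config$intensity_threshold)
  ids <- names(cells) %||% as.character(seq_along(cells))
  rows <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    rows[[i]] <- tryCatch({
      border <- trace_border(sheet, cells[[i]],
                             margin_px = config$trace_margin_px)
      segs <- extract_segments(border, mask, config)
      cov <- junction_coverage(border, segs)
      mor <- cell_morphology(border)
      data.frame(cell_id = ids[i], t(mor), t(cov), n_segments = nrow(segs),
                 channel_name = channel_name)
    }, error = function(e) {
      stop("cell ", ids[i], ": ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("cell_records", "data.frame")
  out
}

#' @export
print.cell_records <- function(x, ...) {
  cat(sprintf("<cell_records> %d cells\n", nrow(x)))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Overlay classified junctions on a sheet image
#'
#' Draws the traced border colored by the phenotype owning each border pixel
#' (continuous green, punctate yellow, perpendicular magenta, uncovered
#' grey) over the junction image - the per-cell classified-junction display.
#'
#' @param sheet the junction [unwrapped_sheet()].
#' @param border a traced [trace_border()] result.
#' @param segments the matching [extract_segments()] result.
#' @param ... passed to [plot.unwrapped_sheet()].
#' @export
plot_cell_overlay <- function(sheet, border, segments, ...) {
  plot(sheet, col = grDevices::gray.colors(256, 0, 1), ...)
  own <- .segment_ownership(border, segments)
  colmap <- c(continuous = "green3", punctate = "yellow",
              perpendicular = "magenta")
  cols <- ifelse(own == "", "grey60", colmap[own])
  ps <- if (inherits(sheet, "unwrapped_sheet")) sheet$pixel_size else c(1, 1)
  graphics::points((border$path[, 2] - 1) * ps[2],
                   (border$path[, 1] - 1) * ps[1],
                   col = cols, pch = 15, cex = 0.3)
  invisible(NULL)
}
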