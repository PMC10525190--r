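# Synthetic vessel scenes with analytic ground truth.
#
# A flat monolayer is built as a seeded jittered-grid tessellation: cells are
# quadrilaterals with exactly shared edges, every interior edge receives one
# junction phenotype, and paint is laid down by rule:
#   continuous    - unbroken 3 px line along the whole edge, run length
#                   >> 15 px;
#   punctate      - 6 px dashes, 5 px gaps, 3 px thick (rho ~ 0.4);
#   perpendicular - 4 px wide axis-aligned strokes crossing the edge
#                   (+-5 px), spaced 11 px apart (rho ~ 2).
# Paint keeps a 7 px margin from every tessellation vertex - beyond the
# default 5 px analysis corridor - so no cell's corridor can capture paint
# belonging to another cell's edges near shared corners.
# Expected per-cell coverages follow analytically from the painted lengths,
# so the whole trace/segment/classify/coverage chain can be validated
# without real data. wrap_to_cylinder() renders a sheet onto a cylindrical
# z-stack using the exact inverse of the unwrap sampling map.

#' Synthetic scene specification
#'
#' Defaults mirror the modeled vessel geometry: an 80 um lumen radius
#' (a 160 um diameter channel), 1.0 um z-spacing with 0.5 um in-plane
#' sampling, and a 0.5 um sheet pixel, so the full circumference is 1005
#' sheet rows.
#'
#' @param sheet_px sheet size (rows, cols) in px.
#' @param pixel_size sheet pixel size (ds, dx) in um.
#' @param grid cell tessellation (rows, cols) of the sheet.
#' @param mix phenotype probabilities (continuous, punctate, perpendicular),
#'   summing to at most 1; the remainder leaves edges unpainted.
#' @param junction_intensity,nucleus_intensity,background intensity levels.
#' @param noise_sigma additive Gaussian noise SD (0 = clean).
#' @param blur_sigma isotropic Gaussian PSF SD in um (0 = none).
#' @param radius cylinder radius in um.
#' @param voxel_size volume voxel sizes (dz, dy, dx) in um.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(sheet_px = c(1005, 600),
                       pixel_size = c(0.5, 0.5),
                       grid = c(10, 6),
                       mix = c(continuous = 0.6, punctate = 0.2,
                               perpendicular = 0.2),
                       junction_intensity = 180,
                       nucleus_intensity = 150,
                       background = 8,
                       noise_sigma = 0,
                       blur_sigma = 0,
                       radius = 80,
                       voxel_size = c(1, 0.5, 0.5)) {
  mix <- as.numeric(mix)
  if (length(mix) != 3 || any(mix < 0) || any(mix > 1) || sum(mix) > 1 + 1e-12)
    stop("`mix` must be 3 probabilities summing to at most 1")
  if (radius <= 0) stop("radius must be positive")
  if (any(c(junction_intensity, nucleus_intensity, background) < 0))
    stop("intensities must be nonnegative")
  if (any(grid < 1)) stop("need at least one cell")
  structure(list(sheet_px = as.integer(sheet_px), pixel_size = pixel_size,
                 grid = as.integer(grid), mix = mix,
                 junction_intensity = junction_intensity,
                 nucleus_intensity = nucleus_intensity,
                 background = background, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma, radius = radius,
                 voxel_size = as.numeric(voxel_size)),
            class = "scene_spec")
}

#' Generate a flat synthetic monolayer with ground truth
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; output is bit-identical for equal seeds.
#' @return list of class `synthetic_scene`: `junction` and `nuclei`
#'   ([unwrapped_sheet()]s), `cells` (closed waypoint sets, one per cell),
#'   and `truth` (vertices, per-edge phenotypes and painted lengths, and the
#'   analytically expected per-cell records).
#' @export
make_flat_monolayer <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, {
    layout <- .make_layout(spec)
    scene <- .render_scene(spec, layout)
    scene$truth$seed <- seed
    scene
  })
}

# Jittered-grid vertices + per-edge phenotype assignment (consumes RNG).
.make_layout <- function(spec) {
  nrp <- spec$sheet_px[1]; ncp <- spec$sheet_px[2]
  gr <- spec$grid[1]; gc <- spec$grid[2]
  ch <- (nrp - 1) / gr; cw <- (ncp - 1) / gc
  j <- 0.03 * min(ch, cw)
  vr <- outer(0:gr, rep(1, gc + 1)) * ch + 1
  vc <- outer(rep(1, gr + 1), 0:gc) * cw + 1
  jr <- matrix(runif((gr + 1) * (gc + 1), -j, j), gr + 1)
  jc <- matrix(runif((gr + 1) * (gc + 1), -j, j), gr + 1)
  jr[c(1, gr + 1), ] <- 0   # boundary vertices stay on the sheet edge
  jc[, c(1, gc + 1)] <- 0
  vr <- round(pmin(pmax(vr + jr, 1), nrp))
  vc <- round(pmin(pmax(vc + jc, 1), ncp))

  # all grid edges carry junctions (the monolayer is confluent; cells at the
  # sheet boundary abut cells outside the field of view)
  edges <- list(); n <- 0
  for (i in 1:(gr + 1)) for (k in 1:gc) {
    n <- n + 1
    edges[[n]] <- data.frame(p0r = vr[i, k], p0c = vc[i, k],
                             p1r = vr[i, k + 1], p1c = vc[i, k + 1])
  }
  for (i in 1:gr) for (k in 1:(gc + 1)) {
    n <- n + 1
    edges[[n]] <- data.frame(p0r = vr[i, k], p0c = vc[i, k],
                             p1r = vr[i + 1, k], p1c = vc[i + 1, k])
  }
  edges <- do.call(rbind, edges)
  ph <- sample(c("continuous", "punctate", "perpendicular", "none"),
               nrow(edges), replace = TRUE,
               prob = c(spec$mix, max(0, 1 - sum(spec$mix))))
  edges$phenotype <- ph
  list(vr = vr, vc = vc, edges = edges)
}

# Paint a stroke band: positions p0 + t*u + o*n for t in [t0, t1], o in
# [-hw, hw]; returns the image with pixels set to `intensity`.
.paint_band <- function(img, p0, u, nvec, t0, t1, hw, intensity) {
  if (t1 <= t0) return(img)
  ts <- seq(t0, t1, by = 0.35)
  os <- seq(-hw, hw, by = 0.35)
  rr <- round(outer(ts * u[1], os * nvec[1], "+") + p0[1])
  cc <- round(outer(ts * u[2], os * nvec[2], "+") + p0[2])
  keep <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  img[cbind(rr[keep], cc[keep])] <- intensity
  img
}

# Render junction + nuclei channels and analytic ground truth from a layout.
.render_scene <- function(spec, layout) {
  nrp <- spec$sheet_px[1]; ncp <- spec$sheet_px[2]
  gr <- spec$grid[1]; gc <- spec$grid[2]
  vr <- layout$vr; vc <- layout$vc
  edges <- layout$edges
  jun <- matrix(spec$background, nrp, ncp)
  margin <- 7

  edges$painted_len <- 0
  for (e in seq_len(nrow(edges))) {
    ph <- edges$phenotype[e]
    if (ph == "none") next
    p0 <- c(edges$p0r[e], edges$p0c[e]); p1 <- c(edges$p1r[e], edges$p1c[e])
    len <- sqrt(sum((p1 - p0)^2))
    if (len < 2 * margin + 6) next
    u <- (p1 - p0) / len
    nv <- c(-u[2], u[1])
    if (ph == "continuous") {
      jun <- .paint_band(jun, p0, u, nv, margin, len - margin, 1.5,
                         spec$junction_intensity)
      edges$painted_len[e] <- len - 2 * margin + 1
    } else if (ph == "punctate") {
      t <- margin; dash <- 6; gap <- 5; tot <- 0
      while (t + dash <= len - margin) {
        jun <- .paint_band(jun, p0, u, nv, t, t + dash, 1.5,
                           spec$junction_intensity)
        tot <- tot + dash + 1
        t <- t + dash + gap
      }
      edges$painted_len[e] <- tot
    } else {
      # exact axis-aligned pixel rectangles crossing the edge: equal-cost
      # crossings keep the traced border on the chord, and the grid-exact
      # footprint keeps the measured run length tight
      horiz <- abs(u[2]) >= abs(u[1])   # edge runs mostly along columns
      t <- margin + 2; foot <- 4; ext <- 5; gap <- 7; tot <- 0
      while (t + foot / 2 <= len - margin) {
        pc <- p0 + t * u
        if (horiz) {
          cols <- (floor(pc[2]) - 1):(floor(pc[2]) + foot - 2)
          rws <- (round(pc[1]) - ext):(round(pc[1]) + ext)
        } else {
          rws <- (floor(pc[1]) - 1):(floor(pc[1]) + foot - 2)
          cols <- (round(pc[2]) - ext):(round(pc[2]) + ext)
        }
        rws <- rws[rws >= 1 & rws <= nrp]
        cols <- cols[cols >= 1 & cols <= ncp]
        jun[rws, cols] <- spec$junction_intensity
        tot <- tot + foot   # foot columns cover an arc of foot - 1, plus 1
        t <- t + foot + gap
      }
      edges$painted_len[e] <- tot
    }
  }

  # cells, nuclei, expected records
  nuc <- matrix(spec$background, nrp, ncp)
  cells <- list()
  exp_rows <- list()
  cid <- 0
  for (i in 1:gr) for (k in 1:gc) {
    cid <- cid + 1
    poly <- rbind(c(vr[i, k], vc[i, k]), c(vr[i, k + 1], vc[i, k + 1]),
                  c(vr[i + 1, k + 1], vc[i + 1, k + 1]),
                  c(vr[i + 1, k], vc[i + 1, k]))
    cells[[cid]] <- waypoint_set(poly, frame = "sheet", closed = TRUE)

    pum <- (poly - 1) * matrix(spec$pixel_size, 4, 2, byrow = TRUE)
    area <- shoelace_area(pum)
    dseg <- pum[c(2:4, 1), ] - pum
    per_um <- sum(sqrt(dseg[, 1]^2 + dseg[, 2]^2))
    hull <- grDevices::chull(pum)
    sol <- area / shoelace_area(pum[hull, , drop = FALSE])

    dpx <- poly[c(2:4, 1), ] - poly
    per_px <- sum(sqrt(dpx[, 1]^2 + dpx[, 2]^2))
    covs <- c(continuous = 0, punctate = 0, perpendicular = 0)
    for (s in 1:4) {
      a <- poly[s, ]; b <- poly[if (s == 4) 1 else s + 1, ]
      m <- .match_edge(edges, a, b)
      if (!is.na(m) && edges$phenotype[m] != "none")
        covs[edges$phenotype[m]] <- covs[edges$phenotype[m]] +
          edges$painted_len[m] / per_px
    }
    exp_rows[[cid]] <- data.frame(
      cell_id = as.character(cid), area_um2 = area, perimeter_um = per_um,
      circularity = 4 * pi * area / per_um^2, solidity = sol,
      coverage_continuous = covs[["continuous"]],
      coverage_punctate = covs[["punctate"]],
      coverage_perpendicular = covs[["perpendicular"]],
      coverage_total = sum(covs))

    ctr <- colMeans(poly)
    a2 <- 0.22 * (max(poly[, 1]) - min(poly[, 1]))
    b2 <- 0.22 * (max(poly[, 2]) - min(poly[, 2]))
    rr <- max(1, floor(ctr[1] - a2)):min(nrp, ceiling(ctr[1] + a2))
    cc <- max(1, floor(ctr[2] - b2)):min(ncp, ceiling(ctr[2] + b2))
    sub <- outer(((rr - ctr[1]) / a2)^2, ((cc - ctr[2]) / b2)^2, "+") <= 1
    nuc[rr, cc][sub] <- spec$nucleus_intensity
  }
  names(cells) <- as.character(seq_along(cells))

  post <- function(img) {
    if (spec$blur_sigma > 0)
      img <- blur2d(img, spec$blur_sigma / spec$pixel_size)
    if (spec$noise_sigma > 0)
      img <- pmax(img + matrix(rnorm(length(img), 0, spec$noise_sigma),
                               nrow(img)), 0)
    img
  }
  prov <- list(synthetic = TRUE)
  structure(list(
    junction = unwrapped_sheet(post(jun), spec$pixel_size, prov),
    nuclei = unwrapped_sheet(post(nuc), spec$pixel_size, prov),
    cells = cells,
    truth = list(vertices = list(vr = vr, vc = vc), edges = edges,
                 expected = do.call(rbind, exp_rows), spec = spec)),
    class = "synthetic_scene")
}

.match_edge <- function(edges, a, b) {
  hit <- (edges$p0r == a[1] & edges$p0c == a[2] &
          edges$p1r == b[1] & edges$p1c == b[2]) |
         (edges$p0r == b[1] & edges$p0c == b[2] &
          edges$p1r == a[1] & edges$p1c == a[2])
  if (any(hit)) which(hit)[1] else NA_integer_
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d cells, %d x %d px sheet\n",
              length(x$cells), nrow(x$junction$data), ncol(x$junction$data)))
  invisible(x)
}

#' Disrupted-junction variant of a scene
#'
#' Synthetic analogue of an inflammatory barrier-disrupting stimulus:
#' converts a fraction of the continuous junction runs (selected in seeded
#' random order until the requested fraction of continuous painted length is
#' reached) into punctate dashes, reducing expected continuous and total
#' coverage by a known amount. The returned scene is re-rendered from the
#' same tessellation.
#'
#' @param scene a [make_flat_monolayer()] result.
#' @param disruption_factor fraction in \[0, 1\] of continuous painted length
#'   to convert.
#' @param seed seed for the selection order (defaults to the scene's own
#'   seed + 1).
#' @return A `synthetic_scene` with updated ground truth.
#' @export
make_disrupted_variant <- function(scene, disruption_factor, seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (disruption_factor < 0 || disruption_factor > 1)
    stop("disruption_factor must be in [0, 1]")
  if (disruption_factor == 0) return(scene)
  seed <- seed %||% ((scene$truth$seed %||% 0) + 1)
  spec <- scene$truth$spec
  layout <- list(vr = scene$truth$vertices$vr, vc = scene$truth$vertices$vc,
                 edges = scene$truth$edges)
  with_seed(seed, {
    ed <- layout$edges
    cont <- which(ed$phenotype == "continuous")
    if (length(cont) > 0) {
      total <- sum(ed$painted_len[cont])
      ord <- sample(cont)
      cum <- cumsum(ed$painted_len[ord])
      ncvt <- if (disruption_factor >= 1) length(ord) else
        which(cum >= disruption_factor * total)[1]
      if (is.na(ncvt)) ncvt <- length(ord)
      ed$phenotype[ord[seq_len(ncvt)]] <- "punctate"
    }
    layout$edges <- ed
    out <- .render_scene(spec, layout)
    out$truth$seed <- seed
    out$truth$disruption_factor <- disruption_factor
    out
  })
}

#' Render a flat sheet onto a cylindrical z-stack
#'
#' Splats every sheet pixel at its cylindrical position (theta = arc / r,
#' axial = column) onto a thin shell at the cylinder radius, using the exact
#' inverse of the unwrap sampling map (bilinear splatting in each
#' cross-section plane), then applies the spec's blur and noise.
#'
#' @param sheet an [unwrapped_sheet()] (e.g. from [make_flat_monolayer()]).
#' @param spec the [scene_spec()] providing radius, voxel sizes, blur, noise.
#' @param seed seed for the noise draw.
#' @return list: `volume` (a [voxel_volume()]) and `circle` (the true circle
#'   model: center, radius, span, theta0).
#' @export
wrap_to_cylinder <- function(sheet, spec, seed = 1) {
  stopifnot(inherits(sheet, "unwrapped_sheet"), inherits(spec, "scene_spec"))
  r <- spec$radius
  ds <- sheet$pixel_size[1]
  n <- nrow(sheet$data)
  if ((n - 1) * ds > 2 * pi * r + ds / 2)
    stop("sheet height exceeds the cylinder circumference; radius too small")
  vs <- spec$voxel_size
  mgn <- 5 + 3 * spec$blur_sigma
  cz <- r + mgn; cy <- r + mgn
  nz <- ceiling((2 * (r + mgn)) / vs[1]) + 1
  ny <- ceiling((2 * (r + mgn)) / vs[2]) + 1
  nx <- ncol(sheet$data)

  # supersample: 3 sub-pixel arc offsets x 5 radial shells, so the splatted
  # shell is dense enough for the unwrap sampler to recover the sheet
  delta <- min(vs[1], vs[2]) / 2
  sub <- c(-1/3, 0, 1/3) * ds
  theta <- (rep(seq_len(n), 3) - 1) * ds / r +
    rep(sub, each = n) / r
  rho <- seq(r - delta, r + delta, length.out = 5)
  zz <- (outer(sin(theta), rho) + cz) / vs[1]   # 0-based fractional indices
  yy <- (outer(cos(theta), rho) + cy) / vs[2]
  z0 <- floor(zz); y0 <- floor(yy)
  fz <- zz - z0; fy <- yy - y0
  lin <- function(zi, yi) as.vector(zi + yi * nz + 1)
  ii <- c(lin(z0, y0), lin(z0 + 1, y0), lin(z0, y0 + 1), lin(z0 + 1, y0 + 1))
  ww <- c((1 - fz) * (1 - fy), fz * (1 - fy), (1 - fz) * fy, fz * fy)
  jj <- rep(rep(seq_len(n), 3 * length(rho)), 4)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nz * ny, n))
  den <- as.numeric(A %*% rep(1, n))

  vol <- array(0, dim = c(nz, ny, nx))
  chunk <- max(1L, floor(8e6 / (nz * ny)))   # cap scratch at ~64 MB
  for (j0 in seq(1, nx, by = chunk)) {
    j1 <- min(nx, j0 + chunk - 1)
    num <- as.matrix(A %*% sheet$data[, j0:j1, drop = FALSE])
    num[den > 0, ] <- num[den > 0, ] / den[den > 0]
    vol[, , j0:j1] <- array(num, dim = c(nz, ny, j1 - j0 + 1))
  }

  if (spec$blur_sigma > 0)
    vol <- blur3d(vol, spec$blur_sigma / vs)
  if (spec$noise_sigma > 0)
    vol <- with_seed(seed, pmax(vol + array(
      rnorm(length(vol), 0, spec$noise_sigma), dim(vol)), 0))

  list(volume = voxel_volume(vol, vs, "synthetic"),
       circle = structure(list(center = c(cz, cy), radius = r,
                               span = 2 * pi, theta0 = 0, residual = 0,
                               n_points = 0L, warnings = character(0)),
                          class = "circle_fit"))
}
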