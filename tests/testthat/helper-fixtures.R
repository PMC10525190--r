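# Shared fixtures: all built in code, nothing stored on disk.

# Small monolayer scene for fast pipeline tests (16 cells of ~100 px).
small_scene <- function(seed = 7, ...) {
  make_flat_monolayer(scene_spec(sheet_px = c(400, 400), grid = c(4, 4), ...),
                      seed = seed)
}

default_config <- function() classifier_config(intensity_threshold = 90)

# Waypoints on a circle in the cross-section frame, in pixel indices.
circle_waypoints <- function(n, radius_um, center_um, voxel_size,
                             noise_sd = 0, span = 2 * pi) {
  th <- seq(0, span, length.out = n + 1)[seq_len(n)]
  z <- center_um[1] + radius_um * sin(th)
  y <- center_um[2] + radius_um * cos(th)
  if (noise_sd > 0) {
    z <- z + rnorm(n, 0, noise_sd)
    y <- y + rnorm(n, 0, noise_sd)
  }
  waypoint_set(cbind(z / voxel_size[1] + 1, y / voxel_size[2] + 1),
               frame = "cross_section")
}

# A volume whose every (z, y) plane is an annulus of the given intensity.
annulus_volume <- function(radius_um = 20, band_um = 6, value = 100,
                           voxel = c(1, 1, 1), nx = 5, margin_um = 5) {
  ext <- radius_um + band_um / 2 + margin_um
  nz <- ceiling(2 * ext / voxel[1]) + 1
  ny <- ceiling(2 * ext / voxel[2]) + 1
  cz <- (nz - 1) / 2 * voxel[1]; cy <- (ny - 1) / 2 * voxel[2]
  zu <- (seq_len(nz) - 1) * voxel[1]
  yu <- (seq_len(ny) - 1) * voxel[2]
  d <- sqrt(outer((zu - cz)^2, (yu - cy)^2, "+"))
  plane <- ifelse(d >= radius_um - band_um / 2 - 1 &
                  d <= radius_um + band_um / 2 + 1, value, 0)
  vol <- array(rep(plane, nx), dim = c(nz, ny, nx))
  list(volume = voxel_volume(vol, voxel),
       circle = structure(list(center = c(cz, cy), radius = radius_um,
                               span = 2 * pi, theta0 = 0, residual = 0),
                          class = "circle_fit"))
}

# Sheet painted with n_stripes equally spaced circumferential stripes.
stripe_sheet <- function(n_rows = 1005, n_cols = 120, n_stripes = 8,
                         value = 100, pixel_size = c(0.5, 0.5)) {
  img <- matrix(0, n_rows, n_cols)
  for (k in seq_len(n_stripes) - 1) {
    r0 <- round(k * n_rows / n_stripes + 1)
    r1 <- round(k * n_rows / n_stripes + n_rows / (2 * n_stripes))
    img[r0:r1, ] <- value
  }
  unwrapped_sheet(img, pixel_size)
}

# Run the C++ tracer directly on a cost grid (1-based endpoints), with the
# same cost definition as trace_border (including the diagonal penalty).
raw_trace <- function(img, a, b, diag_penalty_frac = 0.15) {
  rng <- diff(range(img))
  eps <- 1e-3 * max(rng, 1)
  p <- vesselunwrap:::.min_cost_path_cpp((max(img) - img) + eps,
                                         a[1] - 1, a[2] - 1,
                                         b[1] - 1, b[2] - 1,
                                         1e-9 * (rng + 1),
                                         diag_penalty_frac * rng)
  p + 1
}
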