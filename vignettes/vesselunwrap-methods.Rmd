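---
title: "Methods: unwrapping microvessels and quantifying junction phenotypes"
author: "vesselunwrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unwrapping microvessels and quantifying junction phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselunwrap)
```

# The problem

Brain microvascular endothelial cells grown in a vessel-on-chip line a
cylindrical channel of roughly 160 µm diameter. Barrier integrity is read
out from the *presentation* of tight-junction proteins (ZO-1, Occludin,
Claudin-5) at cell–cell borders: long continuous bands indicate a mature
barrier, while punctate dots and perpendicular protrusions indicate
immature or remodeling junctions. Measuring this on the raw confocal
z-stack is impractical because the monolayer is curved through the whole
stack. The pipeline therefore (i) reconstructs the cylinder geometry from a
few user-placed waypoints, (ii) unwraps the vessel surface into a flat 2D
sheet, and (iii) quantifies junction phenotype coverage and cell morphology
per cell on the sheet.

All physical quantities are micrometres. Volumes are indexed `(z, y, x)`,
sheets `(row = arc position s, col = axial position x)`, R indices are
1-based, and the physical position of index `i` at spacing `d` is
`(i - 1) * d` (pixel-center convention).

# Unwrapping

## Circle fit

The user waypoints the lumen circumference on a `(z, y)` cross-section.
Waypoints are converted to µm (stacks are anisotropic; a typical acquisition
has dz = 1.0 µm and finer in-plane sampling) and fit in two stages:

1. *Algebraic (Kåsa) fit*: linear least squares on
   $x^2 + y^2 = Dx + Ey + F$, closed form, exactly translation- and
   scale-equivariant.
2. *Geometric refinement*: Gauss–Newton on the residuals
   $r_i = \lVert p_i - c\rVert - r$, converging to machine precision within
   a few iterations. The RMS point-to-circle distance is stored as the fit
   residual; a large residual flags tilted or non-circular channels, which
   this package deliberately does not model (one global circle per vessel).

The angular span covered by the waypoints is inferred from the largest gap
between sorted waypoint angles and snapped to $\pi$ (half cylinder) or
$2\pi$ (full cylinder) when within 15°. Note the practical consequence:
detecting a full cylinder requires the largest angular gap to be at most
15°, i.e. roughly 24 or more evenly spread waypoints; with fewer, pass the
span explicitly. The snap threshold is deliberately conservative — a wrong
full-circle guess silently wraps data around the seam, whereas an explicit
span is always honoured.

Angle convention: $\theta$ is measured from the $+y$ direction increasing
towards $+z$, so a surface point at angle $\theta$ sits at
$z = c_z + \rho\sin\theta$, $y = c_y + \rho\cos\theta$. $\theta_0$ defaults
to 0 (full span) and the convention is recorded in every sheet's
provenance.

## Surface resampling

For each sheet row $i$ (angle $\theta_i = \theta_0 + (i-1)\,ds/r$) and each
axial column, intensity is sampled by bilinear interpolation in the
`(z, y)` plane along the radial ray at radii
$r - b/2 \dots r + b/2$ (band width $b$, default 6 µm ≈ one endothelial
monolayer thickness) with radial step $\le \min(dz, dy)/2$, and combined by
max projection (default; robust to small circle-fit error) or mean
projection. Sampling positions are identical for every axial column, so the
bilinear gather is planned once and reused — long channels stream through
without memory growth. Samples outside the volume contribute 0; their
fraction is recorded in the provenance and an error is raised above 25%,
which in practice means the circle does not belong to the stack.

The default circumferential pixel ds is $\min(dz, dy)/2$. Row count is
$\mathrm{round}(\text{span}\cdot r/ds)$, so the sheet height in µm equals
the unrolled arc within one pixel.

## Half stacks

Stacks truncated near the fitted center plane (a common workaround when a
full stack exceeds acquisition or memory limits) unwrap over span $\pi$.
`unwrap_halfstack()` snaps the half's starting angle onto the full-span row
grid, so the rows of a half unwrap agree with the corresponding rows of the
full unwrap to interpolation accuracy (observed agreement ~1e-11 on shared
voxels; the contract in the tests is 1e-6).

# Border tracing

Cell borders are waypointed on the sheet; automation then follows the
staining between consecutive waypoints. The border is the minimum-cost
8-connected path where entering pixel $p$ costs
$(\max I - I(p)) + \varepsilon$ with
$\varepsilon = 10^{-3}\times$ dynamic range — bright staining attracts the
path, and strictly positive costs guarantee shortest-path semantics.

Two details make the tracer deterministic and noise-robust:

* **Tie-breaking.** Among equal-cost paths the tracer prefers the
  geometrically shorter one, then the one closest to the straight waypoint
  chord (summed squared deviation), then a fixed neighbour order (E, NE, N,
  NW, W, SW, S, SE). On a uniform image the trace is therefore exactly the
  digital straight segment.
* **Diagonal-step penalty.** Every minimal 8-connected path between two
  pixels contains the same number of diagonal steps, so adding a constant
  penalty per diagonal step (default 15% of the dynamic range) changes
  nothing on clean images. On noisy images it prevents intensity
  fluctuations smaller than the penalty from pulling the path into zigzag
  detours, which would otherwise inflate the measured run lengths of
  junction segments. The exhaustive-enumeration oracle used in the tests
  carries the same term, so tracer and oracle always optimize the same
  functional.

Consecutive pairwise traces can overlap by a few pixels near waypoint
corners; the concatenated chain is made simple by dropping the smaller loop
at any repeated pixel. The search for each pair runs in a window around the
pair's bounding box (margin 40 px by default) — junction paths in practice
stay near the chord, and the window keeps tracing fast on large sheets.

# Junction segmentation and classification

Junction signal is isolated by a plain threshold (`image >= t`). The
threshold is a per-dataset constant chosen by the analyst and recorded in
the configuration; `otsu_threshold()` suggests a starting value but is never
applied silently.

Mask pixels within a corridor around the traced border (Euclidean disc,
half-width 5 px by default — wide enough to capture junction signal
straddling the border without reaching the next cell) are grouped into
8-connected components. Each component is projected onto the border
*polyline* — a continuous arc-length projection, so staining oriented
across the border projects to a point-like run regardless of how the border
is rasterized. A component becomes one segment with:

* $L$ — path length: the covered border run plus 1 px (a run covering
  pixels at arcs $a \dots a+k$ has $L = k + 1$, matching the convention
  that an $n$-pixel straight run has $L = n$; a component covering the
  whole closed border has $L$ = perimeter);
* $T = \text{area}/L$ — mean thickness;
* $\rho = T/L$ — thickness-to-path-length ratio.

The phenotype rule is the standard one: $L > 15$ px → continuous; otherwise
$\rho > 1.2$ → perpendicular; otherwise punctate. Boundary conventions are
explicit: $L = 15$ exactly is *not* continuous, and $\rho = 1.2$ exactly is
punctate (the strict inequalities own the boundaries). The 15 px cutoff and
1.2 ratio are configurable but default to the published values.

## Coverage

Every border pixel carries an arc share (the mean of its two incident step
weights, 1 or $\sqrt 2$; shares sum exactly to the perimeter). Each pixel
is owned by at most one segment — the longest-$L$ segment wins where runs
overlap — and per-phenotype coverage is the owned share divided by the
perimeter. This makes the conservation law exact by construction:
continuous + punctate + perpendicular coverage equals total coverage, and
total ≤ 1.

## Morphology

* **Area** is the shoelace (polygon) area of the closed border chain. For a
  100 × 100 px square this gives exactly 10 000 µm² at 1 µm pixels; interior
  pixel counting would give 9 801 or 10 201 depending on the boundary
  convention and was rejected for that reason.
* **Perimeter** is the Euclidean length of the Douglas–Peucker-simplified
  border polygon (tolerance 0.7 px, the digitization half-tube). The raw
  $\sqrt2$-weighted chain length overestimates sloped borders by up to 8%
  (≈5% on average around a circle), which would bias circularity down to
  ~0.90 for a perfect disk; the simplified polygon collapses each digital
  straight segment to its chord — exact for axis-aligned borders, unbiased
  for polygonal ones — while preserving genuine wiggles above 0.7 px. (The
  coverage denominator `perimeter_px` remains the exact chain arc, keeping
  conservation exact.)
* **Circularity** $= 4\pi A/P^2$; a rasterized disc of radius 50 px measures
  ≈ 0.98. Discretization can push values slightly above 1.
* **Solidity** $= A/A_{\text{hull}}$ with the hull from the border chain.

Doubling the pixel size doubles perimeter and quadruples area exactly and
leaves circularity and solidity unchanged, since all four are computed from
the same pixel chain.

# The synthetic vessel generator

The generator provides ground truth the pipeline can be held to without any
external data. Design choices:

* **Geometry mirrors the modeled system**: radius 80 µm (160 µm channel),
  dz = 1.0 µm with 0.5 µm in-plane voxels, 0.5 µm sheet pixels (full
  circumference = 1005 rows), cells ~50 µm across.
* **Tessellation** is a seeded jittered grid of quadrilaterals (jitter 3%
  of the cell pitch). Shared edges are exact line segments, so per-cell
  expected coverages and morphology follow analytically from the layout. A
  Voronoi partition would look more organic but has no closed-form shared
  edge bookkeeping without a dedicated geometry dependency; the jittered
  grid keeps the ground truth exact. The small jitter also keeps edges
  near axis-aligned, which matters because the thickness-to-length ratio of
  a perpendicular stroke is measured on the pixel grid: on steeply sloped
  edges a cost-minimal path rides through a stroke diagonally and lengthens
  its run, blurring the punctate/perpendicular boundary — a real
  measurement property, not an artifact, but one the benchmark should
  control.
* **Painting rules** (intensity 180 over background 8): continuous edges
  carry an unbroken ~4 px line; punctate edges carry 6 px dashes with 5 px
  gaps; perpendicular edges carry 4 px × 11 px axis-aligned rectangles
  crossing the edge every 11 px ($\rho \approx 2$). All paint keeps a 7 px
  margin from tessellation vertices — beyond the 5 px analysis corridor —
  so no cell's corridor can capture paint belonging to a neighbouring
  cell's edges. Ground-truth run lengths follow the same $L$ = arc + 1
  convention the classifier uses.
* **Rendering to 3D** splats each sheet pixel onto a thin shell at the
  cylinder radius (3 sub-pixel arc offsets × 5 radial shells, bilinear
  splatting — the adjoint of the unwrap sampler), then applies the spec's
  isotropic Gaussian PSF and additive Gaussian noise (clipped at 0).
  Simplest models that stress thresholding and interpolation; no
  depth-dependent attenuation or realistic confocal PSF.
* **Disruption scenario**: an inflammatory-stimulus analogue converts a
  requested fraction of continuous painted length into punctate dashes
  (edges selected in seeded random order until the fraction is met), so
  expected continuous coverage scales by a known factor.

Everything is bit-deterministic given the seed, and generation restores the
caller's RNG state.

What passing against this generator does **not** show: robustness to uneven
illumination, depth-dependent signal loss, non-circular lumens, or
segmentation of unwaypointed cells. Those are properties of real data the
benchmark deliberately excludes.

# Statistics

Per-cell metrics are compared between groups the conventional way:

* `dagostino_pearson()` implements the omnibus $K^2 = Z_1^2 + Z_2^2$
  normality test (D'Agostino's skewness transform; Anscombe–Glynn kurtosis
  transform; $\chi^2_2$ reference). The implementation agrees with the
  reference scipy implementation to 1e-12 on asymmetric samples; for
  *exactly* zero sample skewness this package returns the mathematical
  $Z_1 = 0$ where scipy substitutes a small positive constant (an artifact
  of the original routine). The sample-size floor is n = 8 (the kurtosis
  transform's validity floor).
* `compare_groups()` gates on normality (both groups' $K^2$ p > α): normal →
  two-sample t (Welch by default — safer for unequal-variance cell pools;
  Student's form by flag), otherwise → Wilcoxon rank-sum, with the choice
  recorded in the output. Groups below n = 8 skip the gate and use the
  rank-sum test.
* Stars follow the conventional legend: \* p < 0.05, \*\* p < 0.01,
  \*\*\* p < 0.001, \*\*\*\* p < 0.0001.
* `summarize_records()` reports raw per-metric p values (matching the usual
  per-metric reporting in this field, which applies no multiplicity
  correction); Holm adjustment is available by flag. Cells are pooled
  across replicates without a nesting correction — whether replicate should
  be a blocking factor is a scientific choice left to the user.

# Problem sizes and numerical conventions

The shipped tests and the acceptance script run entirely on generated
scenes: 16–60-cell sheets for unit and property tests, two 100-cell scenes
(1005 × 1000 px) for the parameter-recovery and group-comparison checks,
500 × n = 500 null simulations for the normality test's type-I error, and
grids of at most 5 × 5 pixels for exhaustive path enumeration (the oracle
is exponential). The full suite runs in about three minutes; the acceptance
script in about one.

Degenerate inputs are rejected loudly rather than repaired: collinear
circle waypoints, waypoints outside the image, closed borders with fewer
than three points, self-intersecting borders handed to morphology, a circle
whose sampled band falls mostly outside the volume, zero-variance samples
in the normality test. Equality cases are documented where they matter:
thresholding uses `>=`, the phenotype boundaries belong to punctate, and
the star legend's boundaries belong to the weaker annotation.

# Known limitations

* One global circle per vessel; tilt and taper surface only through the fit
  residual.
* Junction coverage depends on the analyst's threshold, exactly as in the
  manual workflow; the Otsu helper is a starting point, not a calibration.
* The thin-line limit of the resampler: structures ~2 px wide on the sheet
  round-trip through the cylinder with NCC ≈ 0.93 at default sampling
  (wide structures: ≥ 0.99); measurements on unwrapped real data should use
  ds no coarser than half the in-plane voxel size.
* The punctate/perpendicular boundary is sensitive to border-path geometry
  for structures near the $\rho = 1.2$ cut; the diagonal-step penalty
  controls the noise contribution but steeply sloped borders still blur
  the boundary (see the generator notes above).
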