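---
title: "Methods: quantifying t-tubule networks from 3D label volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying t-tubule networks from 3D label volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its measurement model, the
choices behind it, and what the synthetic validation does and does not show.

## Input model

The unit of analysis is a **label volume**: a 3D integer voxel grid in
(slice/Z, row/Y, column/X) order with anisotropic spacing — the SBF-SEM
regime of ~8–11 nm in-plane pixels against 50 nm sections is the design
point. Labels partition the grid into cytoplasm (cell mask), extracellular
space, and one or more positive object labels for segmented tubular
structures. Voxel centres sit at `(index − 0.5) × spacing`; all physical
quantities are reported in nm, µm², µm³. How the segmentation was produced
(manual tracing, ML, thresholding) is outside the package's scope: the label
volume is the contract.

## Per-object measurements

**Connected components.** Objects are labelled over the union of object
labels with 26-connectivity by default: at 50 nm section steps, a thin tube
crossing sections obliquely frequently touches only diagonally, and
6-connectivity would shred it into spurious fragments. The flag is exposed
(`connectivity = 6`) for isotropic data. Components under `min_voxels`
(default 8) are discarded as segmentation noise and counted in a log
attribute. By contrast, the *extracellular-contact* test that drives
classification always uses strict face adjacency: a diagonal "contact"
across an anisotropic voxel corner is not physical membrane continuity.

**Volume** is voxel count × voxel volume — exact for the voxelized object,
and the natural conservation identity (component volumes sum to the object
voxel total) is tested as such.

**Surface area** is the area of a sub-voxel iso-surface at the 0.5 level of
the 3×3×3 box-filtered binary indicator, extracted by marching tetrahedra
(each voxel cube split into six tetrahedra) with the anisotropic spacing in
the vertex coordinates. Two choices matter here:

- *Pre-smoothing.* On raw binary data, any 0.5-level surface is a chamfered
  staircase and overestimates curved-surface area by ~6–9%; a voxel-scale
  box filter turns the indicator into a locally planar field whose mid-level
  set tracks the true boundary, bringing cylinder-surface error under 1% and
  cube error to ~2% (corner rounding). The same argument, one dimension
  down, applies to contour perimeters — where the bias would propagate
  directly into the equivalent diameter.
- *Open crop faces.* Components cut by the crop window are not capped at the
  window face: smoothing uses replicate padding there, so the mesh simply
  ends. Truncated tubules therefore do not accrue a fictitious cross-section
  disc of area. (Interfaces with the extracellular partition are real
  membrane and are meshed.)

**Equivalent diameter** follows the serial-section convention: every slice a
component crosses contributes one or more closed cross-section contours, and
under the approximation that cross-sections are circles, the diameter is the
mean contour perimeter divided by π. Contours are traced per component (an
object's contour stack never mixes objects), at the 0.5 level of the 3×3
box-smoothed in-plane indicator with linear edge interpolation, stitched
into closed polygons; perimeter is the polygon length and area the shoelace
value. The formula is dimensionally meaningful only with contour =
perimeter; an area-based variant `d = 2·sqrt(mean area / π)` is available
via `diameter_method = "area"` for sensitivity analysis. Slanted tubules
yield elliptical cross-sections and hence overestimate the diameter — a
known property of the convention, not corrected here.

**Longest-branch length** is realized as the maximum geodesic path length
through the component's voxel graph (26-neighbour adjacency, physical edge
weights) from the sarcolemmal attachment voxels to any voxel of the
component, plus half a voxel extent (projected on the component's principal
axis) at either end, since the geodesic runs centre-to-centre. For
a component without attachment the double-sweep pseudo-diameter of the graph
is used. This realizes "longest branch from the membrane to a tip" as a path
length — a bent tubule is credited its curved length, not its chord — without
a topological thinning step: on tubular shapes the through-volume geodesic
and the skeleton path length agree to within the tube radius, and the
lattice overestimate of oblique paths is bounded by the 26-neighbour chamfer
error (< ~8% worst case, ≪ 1% for near-axis-aligned tubules). Straight
5 µm test cylinders recover to ~1%.

**Cell width and length fraction.** The paper-level convention "length
normalized to cell width" needs a width definition, which is not standard.
The package measures, per tubule, the chord of the cell mask along the line
through the attachment point in the direction of the component's first
principal axis; `cell_width = "per_cell"` switches to the per-cell average
of those chords for all tubules of a cell. Length fractions above 1 are
possible for oblique, convoluted tubules and are flagged rather than
clipped.

**Classification.** `tubule` if face-adjacent to extracellular space;
`fragment` if interior with no such contact; `indeterminate` if its only
possible connection leaves through the crop face, where connectivity is
unknowable within the analysed portion. Indeterminate components are
excluded from fragment statistics and counted separately, making the
treatment of window-truncated objects explicit and reversible. On real
greyscale EM, fragments are additionally authenticated by their retained
basement-membrane dark ring; with label-volume input that authentication is
a segmentation-time responsibility.

**Per-cell aggregates.** Tubule density = sarcolemma-connected tubule count
per µm³ of cell volume (cell mask plus embedded objects — tubule lumina are
part of the cell volume); volume fraction = tubule volume / cell volume ×
100; fragment analogues likewise. Components touching the crop boundary are
measured and flagged but retained in density counts: ~100-section analysis
portions necessarily truncate tubules, and silently excluding them would
bias density downward.

**Subsampling.** Diameter and length statistics are conventionally computed
on 15 randomly chosen tubules per cell, while volume and surface area use
all tubules; `subsample_metrics()` reproduces this (uniform, without
replacement, deterministic given its seed, capped at the available count).

## Hierarchical statistics

Tubule-level measurements are clustered — many tubules per cell, several
cells per animal — so region contrasts use a linear mixed model: fixed
region effect, random intercepts for animal and for cell nested in animal,
fitted by **maximum likelihood**. Before fitting, values are screened for
normality (Shapiro–Wilk by default, Lilliefors-corrected KS as the
alternative) and transformed by the first of {identity, log10, sqrt} that
passes at α = 0.05, with a logged decision trace; group means ± s.e. are
always reported on the original scale. Residual normality of the fitted
model is checked and reported.

The fixed-effect p-value uses a Wald t with **containment degrees of
freedom**: region is assigned at the animal level, so df = (number of
animals) − 2, or the cell analogue in reduced designs with a single animal
per region. This is deliberate. On the package's clustered null simulation
(2 regions × 3 animals × 3 cells × 15 observations; animal SD 0.3, cell SD
0.2, residual SD 1; 1000 replicates) the measured type-I error of this
policy is ≈ 0.06, whereas ML-based likelihood-ratio or Satterthwaite-on-ML
p-values land at 0.10–0.11 with so few animals — and a pooled t-test that
ignores clustering rejects ~37% of true nulls. The containment convention is
also what SAS's mixed-model procedure defaults to for this design, which is
the lineage of the analysis being reproduced.

Degenerate designs degrade explicitly: a single animal per region falls back
to cell-level intercepts with a prominent warning; a variance component
estimated at the boundary (0) is dropped and the model refitted (logged),
without changing the containment level — a zero variance estimate does not
change the experimental unit; if no random structure remains the model
collapses to OLS and the classical t-test p-value is reported, which also
makes the no-clustering limit agree exactly with a two-sample t-test.
Tests are two-sided at α = 0.05 throughout; no multiplicity correction is
applied (actual p-values are reported).

Paired before/after comparisons (e.g. ejection fraction at baseline vs eight
weeks post-infarct) use a two-sided paired t-test; an all-zero difference
vector is reported as p = 1 rather than an error.

## The synthetic myocyte generator

`build_scene()` + `voxelize_scene()` produce label volumes with analytic
ground truth. The scene is a slab cell bounded by two sarcolemmal faces
along Z; tubules are cylinders with sinusoidally modulated radius r(s) =
r₀(1 + a·sin(2πs/λ + φ)), perpendicular to one face, one per z-line at 2 µm
spacing along the cell's long axis, with penetration depth drawn from a
truncated Gaussian. Twin pairs (probability `twin_probability`) straddle a
z-line at ±0.3 µm; longitudinal elements (probability
`longitudinal_probability`, never on twins — a branch from a twin would
cross its partner) bridge toward the adjacent z-line without joining it;
dropout removes tubules; fragments are ellipsoids placed in the interior by
rejection sampling so they touch neither tubules, each other, nor any
boundary. Rasterization uses the voxel-centre inclusion rule (unbiased for
volume in expectation); every primitive gets its own label, and the scene →
label mapping is attached to the volume, so recovery tests can match each
measured component to its analytic row exactly.

Default parameters are anchored to healthy ventricular morphology: 200 nm
mean radius (≈ 400 nm diameter), 2 µm z-line spacing, penetration 0.41 ±
0.05 of the cell width, and a cell geometry (10 × 0.8 µm slab, 6 z-lines)
whose density lands near 0.07 tubules/µm³. The `spec_remote()` and
`spec_border()` presets shift radius (225 / 266 nm), penetration (0.49 /
0.52), dropout (0 / 0.3) and fragment load in the directions and magnitudes
characteristic of infarct-remote and infarct-border remodelling. The cell
width is deliberately smaller than a real ventricular myocyte (~20 µm) so
that default phantoms voxelize to ~20M-voxel arrays; per-tubule scales are
preserved, per-cell volume fraction is consequently higher (~3.5%) than in
tissue (~1.8%), since a slab cell one tubule deep over-weights tubule
volume. Analytic ground truth uses quadrature for modulated-radius volume
π∫r(s)²ds, lateral area 2π∫r(s)√(1+r'(s)²)ds plus flat end caps, and
length-averaged 2r(s) for the diameter; composite rows (tubule + branch) are
flagged `approximate` because the junction geometry is corrected only to
first order. With the dilated border radius, twin pairs can touch at the
base (2×306 nm > 600 nm separation) — they then merge into one component,
which is tolerated (and logged) as realistic: twins emerge from the same
sarcolemmal area.

What the generator does **not** emulate: greyscale texture and imaging
noise (input is a label volume; segmentation error is explicitly out of
scope), curved/bent tubule axes, sheet-like tubule morphologies,
basement-membrane rings, and irregular fragment shapes (classification
depends only on connectivity, not shape). Passing recovery tests therefore
validates the measurement chain on clean segmentations; it says nothing
about segmentation quality on real data.

## Numerical and reproducibility choices

- Contour/iso-surface level fixed at 0.5 of the smoothed indicator;
  marching-squares saddles resolved by the cell-centre average; polygons
  closed by a one-voxel zero pad in-plane.
- Components: 26-connectivity default, `min_voxels = 8`, both logged.
- Geodesics: 26-neighbour Dijkstra with exact Euclidean edge weights; no
  isotropic resampling (lengths are computed directly in physical units).
- All randomness flows from explicit seeds; per-cell seeds are derived from
  the master seed by a deterministic 32-bit hash, so studies are reproducible
  file-for-file (the determinism tests compare output bytes).
- Problem sizes in the test-suite: recovery runs use 3 phantom cells × 18
  tubules at (10, 10, 50) nm; classification exactness uses ~130 components
  at (20, 20, 50) nm; the mixed-model calibration uses 1000 simulated
  studies. These sizes keep the full suite in the minutes range while giving
  sub-percent Monte-Carlo noise on the recovery errors.

## Known limitations

- The equivalent diameter inherits the circular-cross-section approximation
  and overestimates for slanted tubules; the area-based variant is provided
  for sensitivity, not as a default.
- Geodesic "longest branch" can shortcut the centreline inside strongly bent
  tubules by up to roughly one tube radius.
- Cell-width-per-tubule is one of several defensible width conventions; the
  per-cell-average alternative is built in, and the choice is recorded in
  every output.
- Surface areas of crop-truncated components exclude the cut faces; whether
  published serial-section surface areas did likewise is generally
  unreported, so cross-study comparison of truncated-object areas carries
  that ambiguity.
- MRC support is mode 1 (int16) label volumes with spacing in the cell
  header; exotic MRC variants are out of scope.
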