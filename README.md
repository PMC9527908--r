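# ttmorph

3D morphometry of cardiomyocyte transverse-tubule (t-tubule) networks from
segmented volumetric electron microscopy, with the hierarchical statistics
needed to compare regions of remodelled myocardium.

## The problem

T-tubules are pipe-like invaginations of the cardiomyocyte surface membrane
that carry the action potential into the cell interior at every z-line
(roughly 2 µm apart). After myocardial infarction the network remodels —
tubules are lost, dilated, elongated, and fragments appear that are no longer
connected to the extracellular space and are therefore electrically orphaned.
Serial block-face scanning electron microscopy (SBF-SEM) resolves this
remodelling in 3D at ~10 nm in-plane / 50 nm section resolution, but turning
a segmented label stack into per-tubule numbers, per-cell densities, and
defensible region comparisons takes a long chain of geometry and statistics.
`ttmorph` implements that chain for anyone quantifying tubular networks from
3D label volumes:

- **Per-tubule morphometry.** For each connected component: voxel volume;
  sub-voxel iso-surface area (marching tetrahedra on the 3×3×3 box-smoothed
  indicator, anisotropic spacing honoured); the contour-based *equivalent
  diameter*

  d_eq = Σᵢ P(contourᵢ) / (n π),

  i.e. the mean perimeter of the per-slice cross-section contours divided by
  π, under the approximation that cross-sections are circles; the
  *longest-branch length* (maximum geodesic path from the sarcolemmal
  attachment through the voxel graph); and the *length fraction* — length
  normalized to the cell width along the penetration axis.
- **Connectivity classification.** A component face-adjacent to the
  extracellular partition is a t-tubule; an interior component is a
  *fragment*; one that reaches the crop face is *indeterminate*.
- **Per-cell aggregates.** Tubule density (count/µm³), volume fraction (%),
  fragment count, density, mean volume and volume fraction.
- **Hierarchical statistics.** Normality screening (Shapiro–Wilk or
  Lilliefors), log10/√ transforms, and linear mixed models (fixed region
  effect; random intercepts for animal and cell-within-animal; maximum
  likelihood; containment degrees of freedom) — because tubule measurements
  are clustered within cells within animals, and pooled t-tests wildly
  inflate false positives on such data.
- **A synthetic myocyte phantom generator** with analytic ground truth
  (tubules at z-lines, radius narrowings/dilations, twin tubules,
  longitudinal elements, dropout, fragments), so the whole pipeline is
  testable without any microscope.

Label volumes are read/written as multi-page 16-bit TIFF (with a JSON
sidecar for spacing and label roles) or MRC2014.

## Worked example

```r
library(ttmorph)

# a healthy-morphology phantom cell: 6 z-lines, ~200 nm tubule radius,
# penetration ~0.41 of the 10 um cell width
scene <- build_scene(spec_control(), seed = 7)
vol   <- voxelize_scene(scene, spacing = c(10, 10, 50))  # (sx, sy, sz) nm
comps <- label_components(vol)
rec   <- measure_components(comps, cell_id = "c1", region = "control")
head(rec[, c("class", "volume_um3", "surface_um2", "diameter_nm",
             "length_um", "length_fraction")])
#>     class volume_um3 surface_um2 diameter_nm length_um length_fraction
#> 1  tubule    0.50252    5.250381    402.3462  3.955922       0.3955922
#> 2  tubule    0.45492    4.771327    400.8042  3.601980       0.3601980
#> 3  tubule    0.44534    4.572858    408.4239  3.401962       0.3401962
#> 4  tubule    0.73207    7.763733    422.9297  5.456985       0.5454258
#> 5  tubule    0.49536    5.220844    401.8876  3.907884       0.3907884
#> 6  tubule    0.51658    5.344120    400.3705  4.102971       0.4102971

cell_summaries(rec, cell_volume(vol))
#>   ... n_tubules tubule_density_um3 tubule_volume_fraction_pct ...
#>             6             0.0625                   3.277906
```

Each row is one connected tubule: a ~400 nm equivalent diameter (the
generator draws a 200 nm mean radius), lengths of 3.4–5.5 µm penetrating
~34–55% of the 10 µm cell width, and a per-cell density of 0.0625
tubules/µm³ in this 96 µm³ cell.

A full three-region study (3 animals × 3 cells per region) and its mixed-model
region contrasts:

```r
st  <- simulate_study(n_animals = 3, n_cells = 3, seed = 42)
res <- run_pipeline(st$config)
subset(res$comparisons, metric == "diameter_nm" & region_b == "border",
       c(metric, region_a, region_b, mean_a, mean_b, p_value))
```

which reports the dilated border-region diameters against control alongside
the mixed-model p-value. A thin command-line wrapper with `simulate`,
`measure` and `all` verbs is installed at `inst/scripts/ttmorph.R`.

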