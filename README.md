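# capnet

Quantification of 3D capillary networks from fluorescence image stacks.

Light-sheet microscopy of optically cleared organs yields 3D greyscale
volumes in which a fluorescent lectin labels the capillary endothelium.
`capnet` turns such a stack into comparable numbers without any visual
thresholding step: it segments tissue and vessels from the greyscale
histogram alone, skeletonizes the vessel mask, extracts the segment/node
graph, and reports the global and per-segment network parameters together
with the distribution fits and nonparametric tests used to compare samples.
A synthetic tubular-phantom generator with exact analytic ground truth
backstops every stage, so the whole pipeline is testable without microscope
data. The intended users are imaging labs quantifying microvascular
architecture (heart, brain, tumour models) and anyone validating vessel
segmentation/skeletonization code against known geometry.

## The method in brief

**Segmentation.** The histogram of a labelled stack holds three populations:
background, non-labelled tissue, labelled vessels. The tissue/background
threshold sits at the inflexion point of the (smoothed) frequency curve
between the first two peaks. The vessel threshold comes from a Gaussian fit
of the tissue population: `t_vessel = mean + 1.96 SD`, which excludes 97.5%
of tissue voxels for every sample — an identical exclusion fraction is what
makes samples comparable. Binarization is followed by a 3×3×3 majority
(median) filter.

**Network.** The vessel mask is thinned to a one-voxel centerline by
distance-ordered homotopic thinning (simple points in the (26,6) topology,
endpoints preserved), fused with the exact Euclidean distance map (local
radius), and parsed into a graph: junction voxel clusters become nodes,
maximal paths become segments with length, mean radius and end-to-end chord.
Artifactual loops (chord = 0) and sub-resolution segments (mean radius < 1
voxel) are removed and the removed percentage reported.

**Parameters.** Per sample: vascular density (%), box-counting
(Minkowski–Bouligand) fractal dimension with regression R², segments/mm³,
nodes/mm³, node percentage, total length (m/mm³). Per segment: length (µm),
diameter = 2 × mean radius (µm), tortuosity = length/chord. Segment length
and tortuosity distributions are fitted by one-phase exponential decay
`F = (F0 − F∞)·e^(−K·x) + F∞` (λ = 1/K, the length constant; τ = 1/K for
tortuosity); diameter distributions by a Gaussian `F = A·e^(−((d−µ)/σ)²/2)`.
Models are compared by F-tests, groups by Kruskal–Wallis with Dunn's
post-hoc.

## Worked example

```r
library(capnet)

# a Y-shaped phantom: 3 segments of 26 um meeting at one node, radius 3 um,
# rendered with the three-population intensity model on a 76x76x24 um grid
net <- make_y_network(arm_length = 26, radius = 3)
ph  <- render_phantom(net, dim = c(76, 76, 24), spacing = 1, seed = 4)

res <- run_pipeline(pipeline_config(), volume = ph$volume)
res$model
#> HistogramModel: t_background = 17, tissue N(100.01, 20.11), t_vessel = mean + 1.96 sd = 139
res$metrics
#> GlobalMetrics (tissue volume 7.393e-05 mm^3):
#>   vascular density     3.17 %
#>   fractal dimension    NA (R^2 = NA)
#>   segments / mm^3      4.058e+04
#>   nodes / mm^3         1.353e+04
#>   node percentage      33.3 %
#>   total length / mm^3  1.025 m
head(res$segments[, 1:4])
#>   id length_um diameter_um tortuosity
#> 1  1  27.16672    5.115515   1.164763
#> 2  2  26.60624    5.071224   1.100033
#> 3  3  22.00000    5.656854   1.000000
```

The segmentation recovers the generating intensity model (tissue N(100, 20))
and places the vessel threshold at 139 = 100 + 1.96 × 20. The three arms come
back as three segments of ~22–27 µm (the junction clump owns the central
voxels, and thresholding noise roughens the two oblique arms slightly), one
node — hence node percentage 33.3% — and diameters within a voxel of the
true 6 µm. The fractal dimension is NA
because a 24-voxel axis leaves fewer than three dyadic box sizes; on full
128³ stacks it is reported (≈2.45 with R² ≥ 0.99 on a dense phantom, the
range reported for ventricular myocardium). `ph$truth` carries the analytic
ground truth (arc lengths, radii, tortuosities, volumes) for comparison.

Real stacks enter through `load_stack("vol.tif", spacing = c(dy, dx, dz))`;
anisotropic spacings are resampled to an isotropic grid before any geometry.
A thin command-line front end with subcommands (`phantom`, `segment`,
`skeletonize`, `metrics`, `fit`, `run`) lives at `inst/cli/capnet.R`.

## Layout

- `R/`, `src/` — implementation (R plus a small Rcpp core: exact 3D EDT,
  topology-preserving thinning, 3×3×3 majority filter)
- `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles
- `vignettes/capillary-network-quantification.Rmd` — the models, parameter
  defaults, numerical conventions and known limitations, in detail
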