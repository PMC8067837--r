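---
title: "Quantifying 3D capillary networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D capillary networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnet)
```

# The problem

Light-sheet microscopy of optically cleared organs produces 3D greyscale
stacks in which a fluorescent lectin labels the capillary endothelium. The
goal is an operator-independent quantification of the capillary network:
which voxels are vessel, what graph the vessels form, and a small set of
comparable numbers per sample. `capnet` implements that pipeline end to end,
plus a synthetic tubular phantom generator whose exact geometric ground
truth backstops every stage.

# The segmentation model

The greyscale histogram of a labelled, cleared-tissue stack contains three
voxel populations in increasing intensity order: image background,
non-labelled tissue, and labelled vessels. Two thresholds separate them.

**Background threshold.** Background and tissue are separated by the
inflexion point of the frequency curve between their peaks. The curve is
first smoothed with a centred moving average (default width 11 grey levels;
the histogram of a multi-million-voxel stack is smooth, and 11 levels span
well under the typical inter-peak distance). The threshold is the first
grey level after the background peak at which the second difference of the
smoothed curve changes sign from negative to positive. If no second peak
exists the input is effectively unimodal and the function refuses to guess;
the threshold must then be supplied manually.

**Vessel threshold.** Tissue and vessel overlap too much for an inflexion
point, but non-labelled tissue is empirically Gaussian. A Gaussian
`A exp(-((g - mean)^2) / (2 sd^2))` is least-squares fitted to the histogram
over a grey window covering the tissue peak, and the vessel threshold is set
at `mean + 1.96 sd`, rounded half-up. Because 95% of a normal population
lies within ±1.96 SD, the threshold excludes 97.5% of tissue voxels; the
same exclusion fraction applies to every sample regardless of its absolute
intensities, which is what makes between-sample comparisons unbiased. The
multiplier is a parameter (`z`), not a constant, so other exclusion levels
are available.

**Tissue-peak fit window.** The window runs from the background threshold to
a symmetric bound `mode + (mode - t_background)`, where the tissue mode is
the *first* histogram peak above the background threshold — not the global
maximum, which on densely vascularized samples (vascular densities above
~30% are routine in myocardium) can be the vessel peak. The window is
additionally capped at the minimum of the smoothed curve between the tissue
and vessel peaks, because with a tall vessel population the symmetric bound
alone would reach into the vessel peak and drag the fitted mean and SD
upward, smearing the fitted tissue population toward the vessel one. Both
choices only affect the default; an explicit `fit_range` overrides them.

**Filtering.** After binarization (tissue mask = voxels ≥ background
threshold; vessel mask = voxels ≥ vessel threshold, hence nested), a 3D
median filter removes isolated noise voxels. On binary data a 3-voxel median
filter is exactly a majority vote over the 3×3×3 neighbourhood, which is how
it is implemented (grid faces are handled by symmetric reflection). A
radius-1.5 spherical neighbourhood would be a defensible alternative
reading of "3 voxels"; the cubic kernel matches the common plugin behaviour
and is what we ship. Note the filter is not idempotent on convex solids —
each pass chamfers corners and edges slightly (a corner voxel keeps only 8
of 27 neighbours) — but interiors more than one voxel from the surface are
never touched, and tube-like structures of radius ≥ 1.5 voxels pass through
essentially unchanged.

# Geometry: resampling, distance map, skeleton, graph

All geometric computation happens on an isotropic grid. Anisotropic stacks
(e.g. 0.5 × 0.5 × 2 µm) are resampled once, to the smallest spacing
component by default — linear interpolation for greyscale, nearest-neighbour
for masks — which resolves every downstream "voxel unit" ambiguity (the
artifact-removal rule "radius below 1 voxel", box sizes, step lengths) in
one place.

The **distance map** is the exact Euclidean distance transform (computed by
the separable lower-envelope algorithm, with per-axis spacing), with the
grid border counted as background so radii are bounded for objects touching
the faces. At a centerline voxel the distance to the nearest background
voxel estimates the local vessel radius.

The **skeleton** is produced by distance-ordered homotopic thinning: border
voxels are deleted in order of increasing distance-map value, and a voxel
may be deleted only if it is a *simple point* in the (26, 6) digital
topology — foreground 26-connectivity and background 6-connectivity are both
preserved — and not a curve endpoint (a voxel with a single foreground
neighbour). Deletion order is deterministic (distance, then linear index),
so skeletons are bit-reproducible. Any topology-preserving thinning would
satisfy the pipeline's contracts; this one was chosen because the distance
ordering keeps the line medial and the endpoint rule preserves segment
extents to within about a voxel.

**Graph extraction** classifies skeleton voxels by their 26-neighbour count
(1 endpoint, 2 path, ≥3 junction). Thinning produces junction *clumps*, so
mutually adjacent junction voxels are merged into one node at their
centroid — the network has junctions, not junction voxels. Junction voxels
belong to nodes, not segments; a segment's path starts at its first
non-junction voxel, so no length is counted twice at nodes (the suite
checks that segment and node voxel counts partition the skeleton exactly).
Per segment we record the path, its length (sum of Euclidean inter-voxel
steps, in µm), its mean distance-map radius, and the chord between its
ends. Closed loops get chord 0 by definition.

Voxel-step lengths are exact for axis-aligned and 45° paths but carry a
staircase bias at intermediate orientations: steps are quantized to the
axis/face-diagonal/space-diagonal classes (1, √2, √3 × spacing), which
inflates oblique path lengths — and therefore tortuosity — by up to ~10%.
Path smoothing before measurement would reduce the bias but would also make
"length" depend on a smoothing parameter; we keep the raw step convention
and note that tortuosity comparisons are fair between samples processed
identically, while absolute oblique tortuosities are slight overestimates.

**Artifact removal** deletes segments with chord 0 (artifactual loops whose
start and end coincide) and segments with mean radius below the resolution
limit (default: one isotropic voxel, in µm). The removed percentage is
reported. Nodes reduced to degree 2 by the removal are *not* re-merged:
removal can create one-to-one junctions between two segments, and we keep
them as two segments rather than silently rewriting the topology.

# The nine parameters

Global (per sample): vascular density (vessel voxels / tissue voxels, %;
the tissue mask includes vessel voxels), box-counting fractal dimension of
the skeleton with the regression R², segment count and node count per mm³
of tissue, node percentage (nodes/segments), and total segment length per
mm³ (m/mm³). Per segment: length (µm), diameter (2 × mean radius, µm), and
tortuosity (length / chord, 1 for a straight vessel).

Box counting uses a single grid origin and dyadic box sizes from 2 voxels up
to a quarter of the smallest grid dimension (2–32 on a 128³ grid); the
dimension is the slope of log N against log(1/s). Offset averaging would
smooth the counts slightly but is not part of the reference convention we
follow; the origin and sizes are arguments.

Reporting utilities cover the specimen-level conversions: the ellipsoid
volume V = 4/3 π (l/2)(w/2)(t/2) from three external dimensions, shrinkage
percentages 100 (before − after)/before, and the areal→volumetric capillary
density conversion n₃D = n₂D / (mean length in mm) — e.g. 2500 capillaries/mm²
at 15 µm mean length is 166,667 ≈ 170,000 capillaries/mm³ at two significant
figures. No shrinkage correction is applied to network metrics: they are
reported on cleared-tissue geometry, and the shrinkage utilities exist for
reporting only.

# Frequency distributions and fits

Segment length, diameter and tortuosity are summarized as relative frequency
distributions over left-closed equal-width classes from the variable's
natural origin (0 for length and diameter, 1 for tortuosity). Default class
widths are 5 µm, 1 µm and 0.1 respectively — matching the granularity at
which such distributions are usually plotted — and are arguments everywhere.

Length and tortuosity distributions are fitted by one-phase exponential
decay `F = (F0 − F∞) e^(−K x) + F∞` (K > 0, F∞ ≥ 0); the reciprocal 1/K is
the length constant λ (µm) or tortuosity constant τ. Diameter distributions
are fitted by `F = A e^(−((d − µ)/σ)²/2)`. Fits use Levenberg–Marquardt
nonlinear least squares with moment-based starts and a deterministic ladder
of perturbed restarts on non-convergence. The tortuosity decay is fitted
over the observed support (t ≥ 1) without shifting, exactly as the equation
is written, even though F0 is formally the frequency at t = 0; λ and τ are
scale parameters and unaffected by this convention. Fits are pooled over all
segments of a group rather than averaged over per-sample fits; with a single
pooled distribution per group that is the only option that uses all segments
symmetrically, and it is documented rather than configurable.

Model choice between the two equal-complexity families uses the variance
ratio F = SSE_worse / SSE_better on (df, df) with the lower-SSE model
preferred (ties are flagged and broken by declaration order). Group
comparison uses the extra-sum-of-squares F-test of one pooled parameter set
against per-group parameter sets.

**A caveat we verified rather than assumed:** the pooled-versus-separate
F-test on binned relative frequencies is anticonservative. Bin noise is
multinomial — variance proportional to p(1−p)/n, so dense bins are orders of
magnitude noisier than near-empty tail bins — which violates the
iid-residual assumption behind the F reference distribution, and simulations
under the null (two groups drawn from the same exponential) reject far more
often than the nominal 5%; an independent reimplementation with another
optimizer reproduces the inflation, so it is a property of the procedure,
not of this implementation. The test is still the field's convention and is
what the package implements; p-values near the threshold should be read
accordingly, while strong effects (e.g. a 3-fold rate difference) remain
unambiguous. Kruskal–Wallis with Dunn's post-hoc
(tie-corrected z-tests on mean ranks, Bonferroni-adjusted by default) is
used for sample-level global parameters and does not share the issue.

# The phantom generator

Phantoms are tube networks: polyline centerlines swept by a constant radius,
voxelized by exact point-to-polyline distance at voxel centres. The tissue
compartment is a filled parallelepiped (the grid minus a background shell);
metrics are normalized per volume, so the compartment's shape is irrelevant
and a heart-shaped phantom would add nothing but code. Intensities are drawn
per compartment from the three-population Gaussian model (defaults:
background N(10, 5), tissue N(100, 20), vessel N(200, 15), on the 8-bit
scale — a separation typical of lectin-labelled cleared myocardium), clipped
to [0, 255] and reproducible from a seed.

Ground truth is analytic: per-tube arc length and tortuosity come from the
same polyline the voxelizer sees, volumes from πr²L. Sinusoidally perturbed
tubes provide closed-form tortuosity targets; the Y-network (three arms, one
junction) is the canonical node-counting fixture; `make_random_network`
scatters randomly oriented tubes (optionally of bounded length) through the
block for density-controlled networks.

The default grid is 128³ at 1 µm isotropic — desk-scale, yet with enough
dyadic box sizes (2–32) for box counting. The dense network used for the
box-count linearity check has 1500 straight tubes of radius 2–2.8 µm,
giving an inter-tube spacing of a few µm and a box-count dimension near
2.45, in the range reported for ventricular myocardium. Linearity of log N
versus log(1/s) needs the skeleton's characteristic spacing to sit at or
below the smallest box size: on sparse phantoms (tens of tubes) the counts
bend between the line-like and volume-filling regimes and the regression R²
degrades — a property of box counting itself, not a failure of the
estimator.

What the phantom does *not* emulate: the microscope point-spread function,
photon/shot noise, clearing artifacts, intensity gradients with depth, and
vessel caliber variation along a tube. Passing the phantom suite therefore
validates the geometry and statistics of the pipeline, not robustness to
optical degradation.

# Numerical conventions and degenerate inputs

16→8-bit conversion linearly rescales observed min→0, max→255 with half-up
rounding (constant volumes map to 0 with a warning). Thresholding is
deliberately per-stack, not per-slice. The vessel threshold caps at 255.
Resampling preserves each axis's physical extent to within one target voxel.
An empty vessel mask yields an empty skeleton with a warning; an empty
tissue mask is an error (density undefined). Fits require at least 4 classes
and refuse histogram windows narrower than 4 grey levels. All randomness is
seed-controlled; seeded helpers restore the caller's RNG state.

# Problem sizes used by the shipped checks

Unit fixtures run at 48³–76³; the box-count linearity check and the
acceptance script use one 128³ phantom (about a minute of compute), 10⁴
samples for fit recovery, and 10⁶ voxels for the threshold-exclusion check.
These sizes were chosen so the full suite exercises every stage at
realistic densities while remaining desk-scale.
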