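#' Volume vascular density
#'
#' Labelled capillary volume as a percentage of the total cardiac volume
#' (non-labelled tissue + capillary network). Both masks live on the same
#' grid, so voxel volumes cancel.
#'
#' @param vessel_mask,tissue_mask 3D logical arrays, vessel within tissue.
#' @return Density in percent.
#' @export
vascular_density <- function(vessel_mask, tissue_mask) {
  nt <- sum(tissue_mask)
  if (nt == 0) stop("empty tissue mask")
  100 * sum(vessel_mask) / nt
}

#' Box-counting (Minkowski-Bouligand) fractal dimension
#'
#' Counts occupied boxes N(s) over dyadic box sizes s (in voxels), from 2 up
#' to a quarter of the smallest grid dimension by default, with a single grid
#' origin. The dimension is the slope of the least-squares line of log N
#' versus log(1/s); the R-squared of that regression indicates how well the
#' structure scales.
#'
#' @param sk a `Skeleton` (or a 3D logical array with `dim` implied).
#' @param sizes dyadic box sizes in voxels; NULL for the default.
#' @return List `(dimension, r_squared, sizes, counts)`.
#' @export
fractal_dimension <- function(sk, sizes = NULL) {
  if (inherits(sk, "Skeleton")) {
    coords <- sk$coords
    d <- sk$dim
  } else {
    stopifnot(is.logical(sk), length(dim(sk)) == 3L)
    coords <- which(sk, arr.ind = TRUE)
    d <- dim(sk)
  }
  if (nrow(coords) == 0L) stop("empty skeleton")
  if (is.null(sizes)) {
    smax <- floor(min(d) / 4)
    sizes <- 2^(1:20)
    sizes <- sizes[sizes <= smax]
  }
  if (length(sizes) < 3L) stop("fewer than 3 usable box sizes")
  counts <- vapply(sizes, function(s) {
    b <- floor((coords - 1L) / s)
    nb <- ceiling(d / s)
    length(unique(b[, 1] + b[, 2] * nb[1] + b[, 3] * nb[1] * nb[2]))
  }, 0)
  fit <- lm(log(counts) ~ log(1 / sizes))
  # R^2 computed directly: summary.lm warns on exact dyadic scalings
  res <- stats::residuals(fit)
  sst <- sum((log(counts) - mean(log(counts)))^2)
  list(dimension = unname(coef(fit)[2]),
       r_squared = if (sst > 0) 1 - sum(res^2) / sst else 1,
       sizes = sizes, counts = counts)
}

#' Segment and node counts per mm^3 of tissue
#'
#' @param g a `CapillaryGraph`.
#' @param tissue_volume_mm3 total cardiac tissue volume in mm^3 (> 0).
#' @return List `(segments_per_mm3, nodes_per_mm3)`.
#' @export
normalized_counts <- function(g, tissue_volume_mm3) {
  stopifnot(tissue_volume_mm3 > 0)
  list(segments_per_mm3 = nrow(g$segments) / tissue_volume_mm3,
       nodes_per_mm3 = nrow(g$nodes) / tissue_volume_mm3)
}

#' Node percentage: 100 x nodes / segments
#'
#' An index of network connectivity; depends on how many segments meet at
#' each node, not on tissue volume.
#'
#' @param g a `CapillaryGraph` with >= 1 segment.
#' @return Percentage.
#' @export
node_percentage <- function(g) {
  ns <- nrow(g$segments)
  if (ns == 0L) stop("no segments")
  100 * nrow(g$nodes) / ns
}

#' Total capillary length per mm^3 of tissue, in m/mm^3
#'
#' @param g a `CapillaryGraph` (segment lengths in µm).
#' @param tissue_volume_mm3 tissue volume in mm^3 (> 0).
#' @return Length density in m/mm^3.
#' @export
total_length_density <- function(g, tissue_volume_mm3) {
  stopifnot(tissue_volume_mm3 > 0)
  sum(g$segments$length) * 1e-6 / tissue_volume_mm3
}

#' Segment diameter from its mean radius
#' @param mean_radius mean radius in µm (>= 0).
#' @return Diameter in µm (2 x radius).
#' @export
segment_diameter <- function(mean_radius) {
  stopifnot(all(mean_radius >= 0))
  2 * mean_radius
}

#' Segment tortuosity: arc length over chord
#'
#' 1 for a perfectly straight segment. Zero chords must have been removed
#' upstream as artifactual loops.
#'
#' @param length segment arc length in µm.
#' @param euclidean chord length between the segment ends in µm (> 0).
#' @return Tortuosity (>= 1 up to discretization).
#' @export
tortuosity <- function(length, euclidean) {
  if (any(euclidean == 0))
    stop("euclidean distance 0: artifactual loop, must be filtered out")
  length / euclidean
}

#' Ellipsoid volume from three diameters
#'
#' The heart is treated as an ellipsoid of length, width and thickness l, w,
#' t: V = 4/3 * pi * (l/2) * (w/2) * (t/2). Units follow the inputs cubed.
#'
#' @param l,w,t positive extents.
#' @return Volume.
#' @export
ellipsoid_volume <- function(l, w, t) {
  stopifnot(l > 0, w > 0, t > 0)
  4 / 3 * pi * (l / 2) * (w / 2) * (t / 2)
}

#' Shrinkage percentage of a dimension or volume
#'
#' 100 x (before - after) / before, e.g. for optical-clearing shrinkage of
#' each heart dimension and of the ellipsoid volume.
#'
#' @param before,after parameter values before/after clearing (before > 0).
#' @return Percent reduction.
#' @export
shrinkage_percent <- function(before, after) {
  stopifnot(all(before > 0))
  100 * (before - after) / before
}

#' Convert an areal capillary density to a volumetric one
#'
#' A 2D count per mm^2 corresponds to a 3D count per mm^3 once divided by the
#' mean capillary length (in mm): n3d = n2d / (mean_length_um * 1e-3).
#'
#' @param n2d capillaries per mm^2.
#' @param mean_length_um mean capillary length in µm (> 0).
#' @param signif_digits optional rounding to significant figures for
#'   reporting (NULL = exact).
#' @return Capillaries per mm^3.
#' @export
areal_to_volumetric_density <- function(n2d, mean_length_um,
                                        signif_digits = NULL) {
  stopifnot(mean_length_um > 0)
  out <- n2d / (mean_length_um * 1e-3)
  if (!is.null(signif_digits)) out <- signif(out, signif_digits)
  out
}

#' All six global network parameters of a segmented sample
#'
#' @param masks a `BinaryMasks` (tissue and vessel masks with spacing).
#' @param g a filtered `CapillaryGraph`.
#' @param sk the `Skeleton` used for the graph (for box counting).
#' @return An object of class `GlobalMetrics`.
#' @export
global_metrics <- function(masks, g, sk) {
  vol_mm3 <- sum(masks$tissue_mask) * prod(masks$spacing) * 1e-9
  # grids too small for 3 dyadic box sizes get NA rather than failing the run
  fd <- tryCatch(fractal_dimension(sk),
                 error = function(e) list(dimension = NA_real_,
                                          r_squared = NA_real_))
  nc <- normalized_counts(g, vol_mm3)
  structure(list(
    vascular_density = vascular_density(masks$vessel_mask, masks$tissue_mask),
    fractal_dimension = fd$dimension,
    fractal_r2 = fd$r_squared,
    segments_per_mm3 = nc$segments_per_mm3,
    nodes_per_mm3 = nc$nodes_per_mm3,
    node_percentage = node_percentage(g),
    total_length_per_mm3 = total_length_density(g, vol_mm3),
    tissue_volume_mm3 = vol_mm3
  ), class = "GlobalMetrics")
}

#' @export
print.GlobalMetrics <- function(x, ...) {
  cat(sprintf(paste0(
    "GlobalMetrics (tissue volume %.4g mm^3):\n",
    "  vascular density     %.2f %%\n",
    "  fractal dimension    %.3f (R^2 = %.4f)\n",
    "  segments / mm^3      %.4g\n",
    "  nodes / mm^3         %.4g\n",
    "  node percentage      %.1f %%\n",
    "  total length / mm^3  %.4g m\n"),
    x$tissue_volume_mm3, x$vascular_density, x$fractal_dimension,
    x$fractal_r2, x$segments_per_mm3, x$nodes_per_mm3, x$node_percentage,
    x$total_length_per_mm3))
  invisible(x)
}

#' Per-segment parameter table (length, diameter, tortuosity)
#'
#' @param g a filtered `CapillaryGraph`.
#' @return Data frame with one row per retained segment: `length_um`,
#'   `diameter_um`, `tortuosity`, plus end coordinates.
#' @export
segment_records <- function(g) {
  s <- g$segments
  data.frame(id = s$id,
             length_um = s$length,
             diameter_um = segment_diameter(s$mean_radius),
             tortuosity = ifelse(s$euclidean > 0, s$length / s$euclidean, NA),
             euclidean_um = s$euclidean,
             a1 = s$a1, a2 = s$a2, a3 = s$a3,
             b1 = s$b1, b2 = s$b2, b3 = s$b3)
}
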