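#' Tube specification for synthetic phantoms
#'
#' A tube is a polyline centerline (physical µm coordinates, one row per
#' point, columns matching the array dimensions y/x/z) swept by a constant
#' radius. Arc length, chord and tortuosity of the polyline are available in
#' closed form, which makes tubes exact ground truth for the network metrics.
#'
#' @param centerline numeric matrix (>= 2 rows, 3 cols), points in µm.
#' @param radius tube radius in µm (> 0).
#' @param label text label.
#' @return An object of class `TubeSpec`.
#' @export
tube_spec <- function(centerline, radius, label = "tube") {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3L, nrow(centerline) >= 2L, radius > 0)
  if (polyline_length(centerline) <= 0) stop("zero arc length")
  structure(list(centerline = centerline, radius = as.numeric(radius),
                 label = as.character(label)),
            class = "TubeSpec")
}

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

polyline_chord <- function(p) sqrt(sum((p[nrow(p), ] - p[1, ])^2))

#' Analytic tortuosity (arc length / chord) of a tube centerline
#' @param t a `TubeSpec`.
#' @return Tortuosity >= 1.
#' @export
tube_tortuosity <- function(t) polyline_length(t$centerline) / polyline_chord(t$centerline)

#' Voxelize a tube on a regular grid
#'
#' A voxel belongs to the tube iff its centre lies within `radius` (µm) of
#' the centerline polyline. Voxel centres sit at `(i - 0.5) * spacing`.
#'
#' @param t a `TubeSpec`.
#' @param dim integer length-3 grid dimensions.
#' @param spacing voxel spacing in µm (scalar or length-3).
#' @return 3D logical array.
#' @export
voxelize_tube <- function(t, dim, spacing = 1) {
  sp <- rep(as.numeric(spacing), length.out = 3)
  dim <- as.integer(dim)
  ext <- dim * sp
  cl <- t$centerline
  if (any(cl < t$radius) ||
      any(sweep(cl, 2, ext) > -t$radius))
    stop("tube does not fit inside the grid with a margin")
  mask <- array(FALSE, dim)
  if (t$radius < min(sp) / 2)
    warning("tube radius below half a voxel: mask may be empty")
  # split long polyline segments so the per-segment bounding boxes stay small
  # (a long oblique segment would otherwise sweep a huge axis-aligned box)
  max_seg <- 8 * min(sp)
  pieces <- list()
  for (s in seq_len(nrow(cl) - 1L)) {
    p0 <- cl[s, ]; q0 <- cl[s + 1L, ]
    k <- max(1L, ceiling(sqrt(sum((q0 - p0)^2)) / max_seg))
    for (u in seq_len(k))
      pieces[[length(pieces) + 1L]] <-
        rbind(p0 + (u - 1) / k * (q0 - p0), p0 + u / k * (q0 - p0))
  }
  for (s in seq_along(pieces)) {
    p <- pieces[[s]][1, ]; q <- pieces[[s]][2, ]
    lo <- pmax(floor((pmin(p, q) - t$radius) / sp), 0)
    hi <- pmin(ceiling((pmax(p, q) + t$radius) / sp) + 1, dim)
    if (any(hi <= lo)) next
    ii <- (lo[1] + 1):hi[1]; jj <- (lo[2] + 1):hi[2]; kk <- (lo[3] + 1):hi[3]
    cx <- (ii - 0.5) * sp[1]; cy <- (jj - 0.5) * sp[2]; cz <- (kk - 0.5) * sp[3]
    g <- expand.grid(x = cx, y = cy, z = cz)
    d <- q - p
    len2 <- sum(d^2)
    tt <- ((g$x - p[1]) * d[1] + (g$y - p[2]) * d[2] + (g$z - p[3]) * d[3]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    dist2 <- (g$x - p[1] - tt * d[1])^2 + (g$y - p[2] - tt * d[2])^2 +
             (g$z - p[3] - tt * d[3])^2
    inside <- dist2 <= t$radius^2
    if (any(inside)) {
      sub <- as.matrix(expand.grid(i = ii, j = jj, k = kk))[inside, , drop = FALSE]
      mask[sub] <- TRUE
    }
  }
  mask
}

#' Three-population intensity model
#'
#' Greyscale model of a cleared-tissue fluorescence stack: dim background,
#' a Gaussian-distributed non-labelled tissue population, and a brighter
#' labelled-vessel population, on the 0-255 scale.
#'
#' @param background,tissue,vessel numeric length-2 `(mean, sd)` grey levels.
#' @return An object of class `IntensityModel`.
#' @export
intensity_model <- function(background = c(10, 5), tissue = c(100, 20),
                            vessel = c(200, 15)) {
  stopifnot(background[1] < tissue[1], tissue[1] < vessel[1],
            all(c(background[2], tissue[2], vessel[2]) >= 0))
  structure(list(background = background, tissue = tissue, vessel = vessel),
            class = "IntensityModel")
}

#' A network of tubes with declared topology
#'
#' @param tubes list of `TubeSpec`.
#' @param n_nodes declared junction count (NA if unknown).
#' @return An object of class `TubeNetwork`.
#' @export
tube_network <- function(tubes, n_nodes = 0L) {
  stopifnot(all(vapply(tubes, inherits, TRUE, "TubeSpec")))
  structure(list(tubes = tubes, n_nodes = n_nodes), class = "TubeNetwork")
}

#' Exact ground truth of a tube network
#'
#' Per-tube arc length, radius, tortuosity and analytic cylinder volume, plus
#' network totals. Volumes are analytic (pi r^2 L); voxel-count volumes follow
#' from the rendered masks.
#'
#' @param net a `TubeNetwork`.
#' @return An object of class `GroundTruth` with a `tubes` data frame and
#'   totals.
#' @export
ground_truth <- function(net) {
  tb <- net$tubes
  df <- data.frame(
    label = vapply(tb, function(t) t$label, ""),
    arc_length_um = vapply(tb, function(t) polyline_length(t$centerline), 0),
    radius_um = vapply(tb, function(t) t$radius, 0),
    tortuosity = vapply(tb, tube_tortuosity, 0),
    volume_um3 = vapply(tb, function(t)
      pi * t$radius^2 * polyline_length(t$centerline), 0)
  )
  structure(list(
    tubes = df,
    n_segments = length(tb),
    n_nodes = net$n_nodes,
    total_length_um = sum(df$arc_length_um),
    vessel_volume_um3 = sum(df$volume_um3)
  ), class = "GroundTruth")
}

#' Y-shaped three-arm network, the canonical junction fixture
#'
#' Three straight tubes meet at the grid centre: 3 segments, 1 node, node
#' percentage 100/3 %. Arms lie in the central z-plane at 120 degrees.
#'
#' @param arm_length arm length in µm (> 4 * radius).
#' @param radius tube radius in µm.
#' @param dim grid dimensions (default cube fitting the arms).
#' @param spacing voxel spacing in µm.
#' @return A `TubeNetwork` (3 tubes, 1 declared node).
#' @export
make_y_network <- function(arm_length, radius, dim = NULL, spacing = 1) {
  stopifnot(arm_length > 4 * radius)
  sp <- rep(as.numeric(spacing), length.out = 3)
  if (is.null(dim)) {
    side <- ceiling(2 * (arm_length + 4 * radius) / min(sp))
    dim <- c(side, side, ceiling(8 * radius / sp[3]))
  }
  dim <- as.integer(dim)
  ctr <- dim * sp / 2
  ang <- c(90, 210, 330) * pi / 180
  tubes <- lapply(seq_along(ang), function(i) {
    tip <- ctr + arm_length * c(cos(ang[i]), sin(ang[i]), 0)
    tube_spec(rbind(ctr, tip), radius, sprintf("arm%d", i))
  })
  tube_network(tubes, n_nodes = 1L)
}

#' Sinusoidally perturbed tube with closed-form tortuosity
#'
#' A straight axis with a transverse sine perturbation, discretized as a
#' polyline; tortuosity truth is the polyline arc/chord ratio, computed
#' analytically from the same polyline the voxelizer sees.
#'
#' @param from,to endpoints in µm.
#' @param radius tube radius in µm.
#' @param amplitude,periods sine perturbation (µm, count); 0 gives a straight tube.
#' @param n_points polyline resolution; NULL picks ~1 point per µm of axis
#'   (2 points for straight tubes).
#' @param label text label.
#' @return A `TubeSpec`.
#' @export
make_sine_tube <- function(from, to, radius, amplitude = 0, periods = 1,
                           n_points = NULL, label = "tube") {
  from <- as.numeric(from); to <- as.numeric(to)
  axis <- to - from
  L <- sqrt(sum(axis^2))
  if (is.null(n_points))
    n_points <- if (amplitude == 0) 2L else max(17L, min(161L, ceiling(L) + 1L))
  u <- axis / L
  # transverse unit vector: any direction orthogonal to the axis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  s <- seq(0, 1, length.out = n_points)
  pts <- outer(s, axis) + rep(from, each = n_points) +
    outer(amplitude * sin(2 * pi * periods * s), v)
  tube_spec(pts, radius, label)
}

#' Random interconnected tube network spanning a block
#'
#' Straight (optionally sine-perturbed) tubes through random interior points
#' with random orientations, clipped to an inner margin box. Dense enough
#' networks intersect and form junctions; node count is therefore not
#' declared (NA).
#'
#' @param n_tubes number of tubes.
#' @param dim grid dimensions.
#' @param spacing voxel spacing in µm.
#' @param radius tube radius in µm (scalar or range to sample uniformly);
#'   default around the observed capillary radius of ~2.4 µm.
#' @param length_um tube length range in µm sampled uniformly, or NULL to
#'   span the whole inner box. Short scattered tubes at high count emulate
#'   the dense, short-segment architecture of the myocardial capillary bed.
#' @param amplitude sine amplitude in µm (0 = straight).
#' @param margin_um clearance kept from the grid faces.
#' @param seed RNG seed.
#' @return A `TubeNetwork` with `n_nodes = NA`.
#' @export
make_random_network <- function(n_tubes = 60, dim = c(128, 128, 128),
                                spacing = 1, radius = c(2, 3),
                                length_um = NULL, amplitude = 3,
                                margin_um = 8, seed = 1) {
  restore <- local_seed(seed); on.exit(restore())
  sp <- rep(as.numeric(spacing), length.out = 3)
  ext <- dim * sp
  lo <- rep(margin_um, 3); hi <- ext - margin_um
  tubes <- vector("list", n_tubes)
  for (i in seq_len(n_tubes)) {
    ctr <- lo + stats::runif(3) * (hi - lo)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    # extent to the inner box boundary in each direction
    tmax <- suppressWarnings(min(ifelse(u > 0, (hi - ctr) / u, (lo - ctr) / u),
                                 na.rm = TRUE))
    tmin <- suppressWarnings(max(ifelse(u > 0, (lo - ctr) / u, (hi - ctr) / u),
                                 na.rm = TRUE))
    if (!is.null(length_um)) {
      L <- stats::runif(1, length_um[1], length_um[length(length_um)])
      tmin <- max(tmin, -L / 2)
      tmax <- min(tmax, tmin + L)
    }
    a <- ctr + tmin * u; b <- ctr + tmax * u
    r <- if (length(radius) == 2L) stats::runif(1, radius[1], radius[2]) else radius
    amp <- min(amplitude, margin_um / 2)
    tubes[[i]] <- make_sine_tube(a, b, r, amplitude = amp,
                                 periods = sample(1:3, 1),
                                 label = sprintf("t%03d", i))
  }
  tube_network(tubes, n_nodes = NA_integer_)
}

#' Render a phantom volume from tubes and an intensity model
#'
#' The tissue compartment is a filled parallelepiped (the grid minus a
#' background shell of `margin_vox` voxels) containing all tubes; voxel
#' intensities are drawn from the Gaussian of their compartment and clipped
#' to [0, 255]. Overlapping tubes are merged in the mask but remain separate
#' rows in the ground truth, flagged via `overlapping`.
#'
#' @param net a `TubeNetwork` (or list of `TubeSpec`).
#' @param im an [intensity_model()].
#' @param dim grid dimensions.
#' @param spacing voxel spacing in µm.
#' @param margin_vox background shell thickness in voxels.
#' @param seed RNG seed (reproducible rendering).
#' @param name volume label.
#' @return List: `volume` (8-bit `VolumeImage`), `vessel_mask`, `tissue_mask`
#'   (logical arrays, vessel included in tissue), `truth` (`GroundTruth`,
#'   augmented with voxel counts), `overlapping` flag.
#' @export
render_phantom <- function(net, im = intensity_model(),
                           dim = c(128, 128, 128), spacing = 1,
                           margin_vox = 4, seed = 1, name = "phantom") {
  if (!inherits(net, "TubeNetwork")) net <- tube_network(net, NA_integer_)
  stopifnot(inherits(im, "IntensityModel"))
  restore <- local_seed(seed); on.exit(restore())
  dim <- as.integer(dim)
  sp <- rep(as.numeric(spacing), length.out = 3)
  vessel <- array(FALSE, dim)
  vox_sum <- 0
  for (t in net$tubes) {
    m <- voxelize_tube(t, dim, sp)
    vox_sum <- vox_sum + sum(m)
    vessel <- vessel | m
  }
  overlapping <- vox_sum > sum(vessel)
  tissue <- array(FALSE, dim)
  idx <- lapply(dim, function(n) (margin_vox + 1):(n - margin_vox))
  tissue[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  tissue <- tissue | vessel
  n <- prod(dim)
  draw <- function(ms, k) pmin(pmax(round_half_up(rnorm(k, ms[1], ms[2])), 0), 255)
  vox <- array(0L, dim)
  comp <- list(list(!tissue, im$background),
               list(tissue & !vessel, im$tissue),
               list(vessel, im$vessel))
  for (cc in comp) {
    sel <- cc[[1]]
    vox[sel] <- as.integer(draw(cc[[2]], sum(sel)))
  }
  gt <- ground_truth(net)
  gt$vessel_voxels <- sum(vessel)
  gt$tissue_voxels <- sum(tissue)
  gt$tissue_volume_um3 <- sum(tissue) * prod(sp)
  list(volume = volume_image(vox, sp, 8L, name),
       vessel_mask = vessel, tissue_mask = tissue,
       truth = gt, overlapping = overlapping)
}

#' Draw reproducible samples from the pipeline's distribution models
#'
#' Raw samples from the two frequency-distribution families used for segment
#' statistics: exponential (scale = the length or tortuosity constant) and
#' Gaussian.
#'
#' @param kind `"exponential"` or `"gaussian"`.
#' @param params list: exponential needs `scale` (> 0); gaussian needs
#'   `mean` and `sd` (>= 0).
#' @param n sample count (>= 1).
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(kind = c("exponential", "gaussian"),
                                params, n, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n >= 1)
  restore <- local_seed(seed); on.exit(restore())
  if (kind == "exponential") {
    if (is.null(params$scale) || params$scale <= 0)
      stop("exponential scale must be > 0")
    rexp(n, rate = 1 / params$scale)
  } else {
    if (is.null(params$mean) || is.null(params$sd) || params$sd < 0)
      stop("gaussian needs mean and sd >= 0")
    rnorm(n, params$mean, params$sd)
  }
}
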