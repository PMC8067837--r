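#' Skeleton object
#'
#' One-voxel-wide centerline of a binary vessel mask: voxel coordinates on
#' the (isotropic) grid, grid dimensions, spacing, and optionally a radius
#' annotation per voxel (after fusion with the distance map).
#'
#' @param coords integer matrix (n x 3) of voxel coordinates (1-based).
#' @param dim grid dimensions.
#' @param spacing voxel spacing in µm (scalar or length-3).
#' @param radius optional per-voxel radius annotation (µm).
#' @return An object of class `Skeleton`.
#' @export
skeleton_from_coords <- function(coords, dim, spacing = 1, radius = NULL) {
  coords <- matrix(as.integer(coords), ncol = 3)
  sp <- rep(as.numeric(spacing), length.out = 3)
  if (!is.null(radius)) stopifnot(length(radius) == nrow(coords),
                                  all(radius >= 0))
  structure(list(coords = coords, dim = as.integer(dim), spacing = sp,
                 radius = radius),
            class = "Skeleton")
}

#' @export
print.Skeleton <- function(x, ...) {
  cat(sprintf("Skeleton: %d voxels on a %s grid, spacing %g um%s\n",
              nrow(x$coords), paste(x$dim, collapse = "x"), x$spacing[1],
              if (is.null(x$radius)) "" else ", radius-annotated"))
  invisible(x)
}

skeleton_mask <- function(sk) {
  m <- array(FALSE, sk$dim)
  m[sk$coords] <- TRUE
  m
}

#' Euclidean distance map of a binary mask
#'
#' Per-voxel Euclidean distance (µm) to the nearest background voxel centre;
#' zero outside the mask. The grid border counts as background, which bounds
#' radii for objects touching the faces. At skeleton voxels the value
#' estimates the local vessel radius.
#'
#' @param mask 3D logical array.
#' @param spacing voxel spacing in µm (scalar or length-3).
#' @return 3D numeric array of distances in µm.
#' @export
distance_map <- function(mask, spacing = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  sp <- rep(as.numeric(spacing), length.out = 3)
  array(cpp_edt3d(as.vector(mask), dim(mask), sp, TRUE), dim(mask))
}

#' Topology-preserving 3D skeletonization
#'
#' Distance-ordered homotopic thinning: border voxels are deleted in order
#' of increasing distance-map value, a voxel being deletable only if it is a
#' simple point in the (26, 6) digital topology (removal preserves both
#' foreground 26-connectivity and background 6-connectivity) and not a curve
#' endpoint. The result is a one-voxel-wide medial line with the same number
#' of connected components as the mask (for masks without cavities).
#'
#' @param mask 3D logical array on an isotropic grid.
#' @param spacing voxel spacing in µm.
#' @return A `Skeleton` (radius not yet annotated).
#' @export
skeletonize <- function(mask, spacing = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  sp <- rep(as.numeric(spacing), length.out = 3)
  if (diff(range(sp)) > 1e-9)
    warning("skeletonize expects an isotropic grid; resample first")
  if (!any(mask)) {
    warning("empty mask: empty skeleton")
    return(skeleton_from_coords(matrix(integer(0), 0, 3), dim(mask), sp))
  }
  d <- cpp_edt3d(as.vector(mask), dim(mask), sp, TRUE)
  kept <- cpp_thin3d(as.vector(mask), dim(mask), d)
  skeleton_from_coords(which(array(kept, dim(mask)), arr.ind = TRUE),
                       dim(mask), sp)
}

#' Fuse a skeleton with a distance map
#'
#' Annotates each skeleton voxel with the distance-map value at its
#' coordinate, i.e. the local radius estimate in µm.
#'
#' @param sk a `Skeleton`.
#' @param rf 3D numeric radius field from [distance_map()].
#' @return The `Skeleton` with `radius` filled in.
#' @export
fuse_skeleton <- function(sk, rf) {
  stopifnot(inherits(sk, "Skeleton"))
  if (!identical(as.integer(dim(rf)), sk$dim))
    stop("grid mismatch between skeleton and radius field")
  sk$radius <- if (nrow(sk$coords)) rf[sk$coords] else numeric(0)
  sk
}

# 26-neighbourhood offsets (excluding the origin), fixed order
offsets26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

# igraph over skeleton voxels with 26-adjacency; vertices indexed 1..n in
# the row order of coords
skeleton_graph <- function(sk) {
  n <- nrow(sk$coords)
  if (n == 0L)
    return(list(g = igraph::make_empty_graph(0, directed = FALSE), lin = integer(0)))
  d <- sk$dim
  lin <- (sk$coords[, 1] - 1L) + (sk$coords[, 2] - 1L) * d[1] +
    (sk$coords[, 3] - 1L) * d[1] * d[2]
  pos <- seq_len(n)
  edges <- vector("list", 13L)
  e_i <- 0L
  for (r in seq_len(nrow(offsets26))) {
    off <- offsets26[r, ]
    # take each unordered pair once
    if (off[3] < 0 || (off[3] == 0 && (off[2] < 0 || (off[2] == 0 && off[1] < 0))))
      next
    nb <- sweep(sk$coords, 2, off, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nl <- (nb[ok, 1] - 1L) + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    m <- match(nl, lin)
    hit <- !is.na(m)
    if (any(hit)) {
      e_i <- e_i + 1L
      edges[[e_i]] <- cbind(pos[ok][hit], m[hit])
    }
  }
  if (e_i) {
    el <- do.call(rbind, edges[seq_len(e_i)])
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  }
  list(g = g, lin = lin)
}

# order the vertices of a path/cycle component; returns vertex ids in walk order
order_component <- function(adj, verts) {
  if (length(verts) == 1L) return(verts)
  deg_in <- vapply(verts, function(v) length(adj[[v]]), 0L)
  start <- if (any(deg_in <= 1L)) verts[which(deg_in <= 1L)[1]] else min(verts)
  ord <- integer(length(verts))
  ord[1] <- start
  prev <- -1L
  for (i in seq_len(length(verts) - 1L)) {
    nxt <- setdiff(adj[[ord[i]]], prev)
    if (length(nxt) == 0L) break
    ord[i + 1L] <- nxt[1]
    prev <- ord[i]
  }
  ord
}

#' Extract the segment/node graph from a fused skeleton
#'
#' Skeleton voxels are classified by their 26-neighbour count: 1 = endpoint,
#' 2 = path, >= 3 = junction. Mutually adjacent junction voxels merge into a
#' single node at their centroid (thinning produces junction clumps; the
#' network has junctions, not junction voxels). Segments are the maximal
#' paths between node/endpoint voxels; junction voxels belong to the node,
#' not to segments, so segment paths start at the first non-junction voxel
#' and no length is double-counted at nodes. Per segment: length = sum of
#' inter-voxel Euclidean steps (µm), mean radius = mean annotated radius
#' along the path, Euclidean distance = chord between the path ends (0 for
#' closed loops).
#'
#' @param sk a `Skeleton`, ideally radius-annotated via [fuse_skeleton()].
#' @return An object of class `CapillaryGraph`: `segments` data frame,
#'   `paths` (list of coordinate matrices), `nodes` data frame, `n_endpoints`,
#'   `removed_fraction` (%), `spacing`, `dim`.
#' @export
extract_graph <- function(sk) {
  stopifnot(inherits(sk, "Skeleton"))
  sp <- sk$spacing
  sg <- skeleton_graph(sk)
  g <- sg$g
  n <- nrow(sk$coords)
  empty_seg <- data.frame(id = integer(0), length = numeric(0),
                          euclidean = numeric(0), mean_radius = numeric(0),
                          n_voxels = integer(0),
                          a1 = integer(0), a2 = integer(0), a3 = integer(0),
                          b1 = integer(0), b2 = integer(0), b3 = integer(0),
                          node_a = integer(0), node_b = integer(0))
  if (n == 0L)
    return(structure(list(segments = empty_seg, paths = list(),
                          nodes = data.frame(id = integer(0), y = numeric(0),
                                             x = numeric(0), z = numeric(0),
                                             n_voxels = integer(0)),
                          n_endpoints = 0L, removed_fraction = 0,
                          spacing = sp, dim = sk$dim),
                     class = "CapillaryGraph"))
  deg <- igraph::degree(g)
  junction <- deg >= 3L
  # nodes: 26-connected clusters of junction voxels
  node_id <- rep(NA_integer_, n)
  nodes <- data.frame(id = integer(0), y = numeric(0), x = numeric(0),
                      z = numeric(0), n_voxels = integer(0))
  if (any(junction)) {
    sub <- igraph::induced_subgraph(g, which(junction))
    comp <- igraph::components(sub)$membership
    node_id[which(junction)] <- comp
    cents <- t(vapply(seq_len(max(comp)), function(k) {
      colMeans(sk$coords[which(junction)[comp == k], , drop = FALSE])
    }, numeric(3)))
    nodes <- data.frame(id = seq_len(max(comp)), y = cents[, 1],
                        x = cents[, 2], z = cents[, 3],
                        n_voxels = as.integer(table(comp)))
  }
  # adjacency list once, used for walking and node attachment
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  # segments: components after junction removal (remaining degrees <= 2)
  keep <- which(!junction)
  segs <- empty_seg
  paths <- list()
  if (length(keep)) {
    sub <- igraph::induced_subgraph(g, keep)
    comp <- igraph::components(sub)$membership
    adj_sub <- lapply(igraph::as_adj_list(sub), as.integer)
    for (k in seq_len(max(comp))) {
      verts_sub <- which(comp == k)
      ord_sub <- order_component(adj_sub, verts_sub)
      verts <- keep[ord_sub]
      pc <- sk$coords[verts, , drop = FALSE]
      step_len <- function(a, b) sqrt(sum(((b - a) * sp)^2))
      len <- if (nrow(pc) > 1) {
        dmat <- sweep(pc[-1, , drop = FALSE] - pc[-nrow(pc), , drop = FALSE],
                      2, sp, `*`)
        sum(sqrt(rowSums(dmat^2)))
      } else 0
      # a component whose vertices all have degree 2 within it is a closed loop
      closed <- length(verts_sub) >= 3L &&
        all(vapply(verts_sub, function(v) length(adj_sub[[v]]), 0L) == 2L)
      if (closed) len <- len + step_len(pc[nrow(pc), ], pc[1, ])
      eucl <- if (closed) 0 else step_len(pc[1, ], pc[nrow(pc), ])
      mr <- if (!is.null(sk$radius)) mean(sk$radius[verts]) else NA_real_
      # node attachment at each free end (NA if the end is a true endpoint)
      att <- function(v) {
        nb_nodes <- node_id[adj[[v]]]
        nb_nodes <- nb_nodes[!is.na(nb_nodes)]
        if (length(nb_nodes)) nb_nodes[1] else NA_integer_
      }
      segs <- rbind(segs, data.frame(
        id = k, length = len, euclidean = eucl, mean_radius = mr,
        n_voxels = nrow(pc),
        a1 = pc[1, 1], a2 = pc[1, 2], a3 = pc[1, 3],
        b1 = pc[nrow(pc), 1], b2 = pc[nrow(pc), 2], b3 = pc[nrow(pc), 3],
        node_a = if (closed) NA_integer_ else att(verts[1]),
        node_b = if (closed) NA_integer_ else att(verts[nrow(pc)])))
      paths[[length(paths) + 1L]] <- pc
    }
    segs$id <- seq_len(nrow(segs))
  }
  structure(list(segments = segs, paths = paths, nodes = nodes,
                 n_endpoints = sum(deg <= 1L), removed_fraction = 0,
                 spacing = sp, dim = sk$dim),
            class = "CapillaryGraph")
}

#' @export
print.CapillaryGraph <- function(x, ...) {
  cat(sprintf("CapillaryGraph: %d segments, %d nodes, %d endpoints (%.2f%% removed as artifacts)\n",
              nrow(x$segments), nrow(x$nodes), x$n_endpoints,
              x$removed_fraction))
  invisible(x)
}

#' Remove artifactual loops and sub-resolution segments
#'
#' Segments whose Euclidean distance is 0 (closed loops: start and end
#' coincide) and segments with mean radius below the resolution limit
#' (default: one isotropic voxel, in µm) are removed. The removed percentage
#' of the pre-filter segment count is recorded. Nodes left with degree 2 are
#' not re-merged: removal may generate one-to-one junctions between two
#' segments, which are retained as such.
#'
#' @param g a `CapillaryGraph`.
#' @param min_radius resolution limit in µm (default: one voxel).
#' @return The filtered `CapillaryGraph` with `removed_fraction` set (%).
#' @export
filter_artifacts <- function(g, min_radius = NULL) {
  stopifnot(inherits(g, "CapillaryGraph"))
  if (is.null(min_radius)) min_radius <- min(g$spacing)
  n0 <- nrow(g$segments)
  if (n0 == 0L) return(g)
  rad <- g$segments$mean_radius
  bad <- g$segments$euclidean == 0 | (!is.na(rad) & rad < min_radius)
  g$paths <- g$paths[!bad]
  g$segments <- g$segments[!bad, , drop = FALSE]
  if (nrow(g$segments)) g$segments$id <- seq_len(nrow(g$segments))
  g$removed_fraction <- 100 * sum(bad) / n0
  g
}
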