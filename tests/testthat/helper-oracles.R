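# Independent oracles used across the suite. These deliberately use naive
# algorithms (exhaustive search, direct tallies) so they share no code with
# the implementation they check.

# brute-force Euclidean distance map: for each foreground voxel, the minimum
# distance to any background voxel centre, the grid border counting as
# background (virtual outside layer)
brute_edt <- function(mask, spacing = 1) {
  sp <- rep(spacing, length.out = 3)
  d <- dim(mask)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  out <- array(0, d)
  for (r in seq_len(nrow(fg))) {
    p <- fg[r, ]
    best <- min((pmin(p, d - p + 1) * sp))  # straight to the nearest face
    if (nrow(bg)) {
      dd <- sqrt(((bg[, 1] - p[1]) * sp[1])^2 +
                 ((bg[, 2] - p[2]) * sp[2])^2 +
                 ((bg[, 3] - p[3]) * sp[3])^2)
      best <- min(best, dd)
    }
    out[p[1], p[2], p[3]] <- best
  }
  out
}

# number of 26-connected components of a binary 3D array (BFS flood fill)
count_components26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  coords <- which(mask, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(coords))) {
    p <- coords[r, ]
    if (lab[p[1], p[2], p[3]] > 0L) next
    cur <- cur + 1L
    queue <- matrix(p, 1)
    lab[p[1], p[2], p[3]] <- cur
    while (nrow(queue)) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2, v, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        if (mask[nb[q, 1], nb[q, 2], nb[q, 3]] &&
            lab[nb[q, 1], nb[q, 2], nb[q, 3]] == 0L) {
          lab[nb[q, 1], nb[q, 2], nb[q, 3]] <- cur
          queue <- rbind(queue, nb[q, , drop = FALSE])
        }
      }
    }
  }
  cur
}

# straight axis-aligned tube through voxel centres, returning both the
# TubeSpec and the grid it fits
straight_tube_fixture <- function(radius = 3, length = 30, pad = 6) {
  side <- 2 * (radius + pad) + 1
  mid <- (radius + pad) + 0.5  # voxel-centre coordinate in µm at spacing 1
  from <- c(mid, mid, pad + 0.5)
  to <- c(mid, mid, pad + 0.5 + length)
  list(tube = tube_spec(rbind(from, to), radius),
       dim = c(side, side, ceiling(length + 2 * pad + 1)),
       from = from, to = to)
}

# digital solid ball (voxel centres within radius of the centre voxel)
ball_mask <- function(radius, pad = 2) {
  side <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  g <- expand.grid(i = 1:side, j = 1:side, k = 1:side)
  inside <- (g$i - ctr)^2 + (g$j - ctr)^2 + (g$k - ctr)^2 <= radius^2
  array(inside, c(side, side, side))
}

# solid torus mask: tube radius r around a circle of radius R in the central
# z-plane
torus_mask <- function(R = 8, r = 2.2, pad = 4) {
  side <- 2 * (R + r + pad) + 1
  ctr <- (side + 1) / 2
  g <- expand.grid(i = 1:side, j = 1:side, k = 1:side)
  rho <- sqrt((g$i - ctr)^2 + (g$j - ctr)^2)
  inside <- (rho - R)^2 + (g$k - ctr)^2 <= r^2
  array(inside, c(side, side, side))
}
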