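test_that("distance map equals brute-force nearest-background search", {
  set.seed(5)
  for (rep in 1:4) {
    d <- sample(6:14, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < 0.6, d)
    expect_equal(distance_map(mask, 1), brute_edt(mask, 1), tolerance = 1e-12)
  }
  # anisotropic spacing
  mask <- array(runif(10 * 8 * 6) < 0.5, c(10, 8, 6))
  expect_equal(distance_map(mask, c(0.5, 0.5, 2)),
               brute_edt(mask, c(0.5, 0.5, 2)), tolerance = 1e-12)
})

test_that("distance map handles canonical cases", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  expect_equal(distance_map(m, 1)[5, 5, 5], 1)

  ball <- ball_mask(5)
  ctr <- (dim(ball)[1] + 1) / 2
  dc <- distance_map(ball, 1)[ctr, ctr, ctr]
  expect_lt(abs(dc - 5), 0.51)

  # all-foreground grid: border counts as background
  full <- array(TRUE, c(9, 9, 9))
  df <- distance_map(full, 1)
  expect_equal(df[1, 1, 1], 1)
  expect_equal(df[5, 5, 5], 5)
  expect_equal(df, brute_edt(full, 1), tolerance = 1e-12)
})

test_that("skeleton of a straight tube is a single path with two endpoints", {
  fx <- straight_tube_fixture(radius = 3, length = 24)
  mask <- voxelize_tube(fx$tube, fx$dim, 1)
  sk <- skeletonize(mask, 1)
  expect_equal(count_components26(capnet:::skeleton_mask(sk)), 1L)
  g <- extract_graph(sk)
  expect_equal(nrow(g$segments), 1L)
  expect_equal(nrow(g$nodes), 0L)
  expect_equal(g$n_endpoints, 2L)
  # skeleton stays inside the mask
  expect_true(all(mask[sk$coords]))
})

test_that("skeleton topology: Y-junction and torus loop", {
  net <- make_y_network(26, 2.5)
  ph <- render_phantom(net, im = intensity_model(c(10, 0), c(100, 0), c(200, 0)),
                       dim = c(76, 76, 22), seed = 2)
  sk <- skeletonize(ph$vessel_mask, 1)
  g <- extract_graph(sk)
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(nrow(g$segments), 3L)

  tor <- torus_mask(R = 8, r = 2.2)
  skt <- skeletonize(tor, 1)
  gt <- extract_graph(skt)
  expect_equal(gt$n_endpoints, 0L)
  expect_equal(count_components26(capnet:::skeleton_mask(skt)), 1L)
  expect_equal(nrow(gt$segments), 1L)
  expect_equal(gt$segments$euclidean, 0)

  expect_warning(sk0 <- skeletonize(array(FALSE, c(5, 5, 5)), 1), "empty")
  expect_equal(nrow(sk0$coords), 0L)
})

test_that("skeletonization preserves connected component count", {
  set.seed(23)
  m <- array(FALSE, c(40, 40, 16))
  t1 <- tube_spec(rbind(c(8.5, 8.5, 3.5), c(8.5, 30.5, 12.5)), 2)
  t2 <- tube_spec(rbind(c(30.5, 8.5, 3.5), c(30.5, 30.5, 3.5)), 2)
  m <- voxelize_tube(t1, c(40, 40, 16), 1) | voxelize_tube(t2, c(40, 40, 16), 1)
  expect_equal(count_components26(m), 2L)
  sk <- skeletonize(m, 1)
  expect_equal(count_components26(capnet:::skeleton_mask(sk)), 2L)
})

test_that("fusion annotates the skeleton with local radii", {
  fx <- straight_tube_fixture(radius = 3, length = 24)
  mask <- voxelize_tube(fx$tube, fx$dim, 1)
  sk <- fuse_skeleton(skeletonize(mask, 1), distance_map(mask, 1))
  expect_true(all(sk$radius >= 0))
  # interior voxels (away from the tube ends) carry radius close to 3
  mid <- sk$coords[, 3] > 12 & sk$coords[, 3] < max(sk$coords[, 3]) - 6
  expect_equal(mean(sk$radius[mid]), 3, tolerance = 0.2)

  expect_error(fuse_skeleton(sk, array(0, c(2, 2, 2))), "mismatch")
  esk <- skeleton_from_coords(matrix(integer(0), 0, 3), c(5, 5, 5), 1)
  expect_equal(length(fuse_skeleton(esk, array(0, c(5, 5, 5)))$radius), 0L)
})

test_that("graph extraction measures path lengths by Euclidean steps", {
  # straight 11-voxel axis path: length 10, euclidean 10
  coords <- cbind(5L, 5L, 3:13)
  sk <- skeleton_from_coords(coords, c(10, 10, 16), 1)
  g <- extract_graph(sk)
  expect_equal(nrow(g$segments), 1L)
  expect_equal(g$segments$length, 10)
  expect_equal(g$segments$euclidean, 10)
  expect_equal(tortuosity(g$segments$length, g$segments$euclidean), 1)

  # one in-plane diagonal step contributes sqrt(2)
  coords2 <- rbind(c(5L, 5L, 3L), c(5L, 5L, 4L), c(5L, 6L, 5L))
  g2 <- extract_graph(skeleton_from_coords(coords2, c(10, 10, 10), 1))
  expect_equal(g2$segments$length, 1 + sqrt(2))

  # spacing scales lengths
  g3 <- extract_graph(skeleton_from_coords(coords, c(10, 10, 16), 0.5))
  expect_equal(g3$segments$length, 5)
})

test_that("length >= euclidean for every segment of a noisy phantom", {
  net <- make_random_network(25, dim = c(64, 64, 64), radius = c(2, 2.6),
                             length_um = c(15, 35), seed = 31)
  ph <- render_phantom(net, dim = c(64, 64, 64), seed = 31)
  seg <- segment_volume(ph$volume)
  sk <- fuse_skeleton(skeletonize(seg$masks$vessel_mask, 1),
                      distance_map(seg$masks$vessel_mask, 1))
  g <- extract_graph(sk)
  expect_true(all(g$segments$length >= g$segments$euclidean - 1e-9))
  expect_true(all(g$segments$mean_radius >= 0))
})

test_that("artifact filter removes loops and thin segments, tracks percentage", {
  # closed diamond loop (euclidean 0; diagonal steps avoid corner chords
  # that would register as junction voxels) plus one straight path
  cx <- 8L
  loop <- unique(rbind(
    cbind(cx - 4L + 0:4, cx - 0:4, 5L), cbind(cx + 0:4, cx - 4L + 0:4, 5L),
    cbind(cx + 4L - 0:4, cx + 0:4, 5L), cbind(cx - 0:4, cx + 4L - 0:4, 5L)))
  line <- cbind(15L, 3:12, 5L)
  coords <- rbind(loop, line)
  sk <- skeleton_from_coords(coords, c(16, 16, 10), 1,
                             radius = rep(2, nrow(coords)))
  g <- extract_graph(sk)
  expect_equal(nrow(g$segments), 2L)
  expect_true(any(g$segments$euclidean == 0))
  gf <- filter_artifacts(g)
  expect_equal(nrow(gf$segments), 1L)
  expect_equal(gf$removed_fraction, 50)
  expect_true(all(gf$segments$euclidean > 0))

  # no artifacts: unchanged, 0%
  g1 <- extract_graph(skeleton_from_coords(line, c(16, 16, 10), 1,
                                           radius = rep(2, nrow(line))))
  gf1 <- filter_artifacts(g1)
  expect_equal(nrow(gf1$segments), 1L)
  expect_equal(gf1$removed_fraction, 0)

  # sub-resolution mean radius removed
  g2 <- extract_graph(skeleton_from_coords(line, c(16, 16, 10), 1,
                                           radius = rep(0.4, nrow(line))))
  expect_equal(nrow(filter_artifacts(g2, min_radius = 1)$segments), 0L)
})

test_that("tube phantoms are recovered: counts exact, length and diameter close", {
  net <- make_y_network(26, 3)
  ph <- render_phantom(net, dim = c(76, 76, 26), seed = 41)
  seg <- segment_volume(ph$volume)
  sk <- fuse_skeleton(skeletonize(seg$masks$vessel_mask, 1),
                      distance_map(seg$masks$vessel_mask, 1))
  g <- filter_artifacts(extract_graph(sk))
  gt <- ground_truth(net)
  expect_equal(nrow(g$segments), gt$n_segments)
  expect_equal(nrow(g$nodes), gt$n_nodes)
  # total recovered length within 5% of the polyline truth
  expect_equal(sum(g$segments$length), gt$total_length_um, tolerance = 0.05)
  # mean diameter within 1 voxel of the true 6 µm
  expect_lt(abs(mean(segment_diameter(g$segments$mean_radius)) - 6), 1)
})

test_that("segment lengths sum to the skeleton path length without double counting", {
  net <- make_y_network(26, 2.5)
  ph <- render_phantom(net, im = intensity_model(c(10, 0), c(100, 0), c(200, 0)),
                       dim = c(76, 76, 22), seed = 2)
  sk <- skeletonize(ph$vessel_mask, 1)
  g <- extract_graph(sk)
  # every skeleton voxel is owned by exactly one segment or one node
  n_owned <- sum(g$segments$n_voxels) + sum(g$nodes$n_voxels)
  expect_equal(n_owned, nrow(sk$coords))
})
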