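test_that("pose interpolation is slerp + lerp with exact endpoints", {
  p0 <- pose_sample(0, c(1, 0, 0, 0), c(0, 0, 0))
  p1 <- pose_sample(1, quat_from_axis_angle(c(0, 0, 1), pi / 2), c(2, 0, 0))
  # identity pair
  pi_ <- interpolate_pose(pose_sample(0), pose_sample(1), 0.3)
  expect_equal(pi_$q, c(1, 0, 0, 0))
  expect_equal(pi_$p, c(0, 0, 0))
  # midpoint of a 90-degree z rotation is 45 degrees
  mid <- interpolate_pose(p0, p1, 0.5)
  expect_equal(mid$q, quat_from_axis_angle(c(0, 0, 1), pi / 4), tolerance = 1e-12)
  expect_equal(mid$p, c(1, 0, 0))
  # endpoints exactly, for random pose pairs
  set.seed(3)
  for (i in 1:5) {
    q0 <- rnorm(4); q1 <- rnorm(4)
    a <- pose_sample(0, q0, rnorm(3)); b <- pose_sample(1, q1, rnorm(3))
    expect_equal(interpolate_pose(a, b, 0)$q, a$q, tolerance = 1e-12)
    expect_equal(interpolate_pose(a, b, 1)$p, b$p, tolerance = 1e-12)
  }
  expect_error(interpolate_pose(p0, p1, 1.5), "outside")
})

test_that("deskew is the identity under a static trajectory", {
  set.seed(1)
  pc <- point_cloud(rnorm(20), rnorm(20), rnorm(20), t = runif(20, 0, 0.1))
  traj <- list(pose_sample(0), pose_sample(0.1))
  out <- deskew_points(pc, traj)
  expect_equal(xyz(out), xyz(pc), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a single point is transformed by exactly its interpolated pose", {
  q1 <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  traj <- list(pose_sample(0, c(1, 0, 0, 0), c(0, 0, 0)),
               pose_sample(0.1, q1, c(1, 0, 0)))
  pc <- point_cloud(1, 0, 0, t = 0.05)
  out <- deskew_points(pc, traj, t_ref = 0)
  po <- interpolate_pose(traj[[1]], traj[[2]], 0.05)
  expected <- as.vector(stemscan:::quat_to_rotmat(po$q) %*% c(1, 0, 0)) + po$p
  expect_equal(unlist(xyz(out)[1, ]), expected, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(deskew_points(point_cloud(1, 0, 0, t = 0.5), traj), "not covered")
})

test_that("deskew reduces plane-fit residual for a moving sensor", {
  traj <- lapply(seq(0, 0.1, by = 1 / 300), function(ti)
    pose_sample(ti, c(1, 0, 0, 0), c(10 * ti, 0, 0)))   # 10 m/s, harsh skew
  fr <- generate_scan_frame(plane_scene(tilt = 0.3), traj, rows = 8, cols = 360)
  plane_rms <- function(m) {
    X <- cbind(m[, 1], m[, 2], 1)
    r <- m[, 3] - X %*% qr.solve(X, m[, 3])
    sqrt(mean(r^2))
  }
  raw_rms <- plane_rms(xyz(fr$cloud))
  de <- deskew_points(fr$cloud, traj, t_ref = 0)
  expect_equal(n_points(de), n_points(fr$cloud))
  expect_lt(plane_rms(xyz(de)), raw_rms)
  expect_lt(plane_rms(xyz(de)), 1e-6)     # noiseless: deskew is exact
})

test_that("neighborhood covariance ranks degenerate geometries correctly", {
  line <- cbind(seq(0, 1, length.out = 11), 0, 0)
  st <- neighborhood_stats(line, 6)
  expect_equal(st$eigvals[2], 0, tolerance = 1e-12)
  expect_equal(st$eigvals[3], 0, tolerance = 1e-12)
  expect_gt(st$lam, 0)
  set.seed(2)
  plane <- cbind(runif(11), runif(11), 0)
  sp <- neighborhood_stats(plane, 6)
  expect_equal(sp$eigvals[3], 0, tolerance = 1e-12)
  expect_gt(sp$eigvals[2], 0)
  # degenerate: fewer than 3 distinct points
  same <- matrix(1, 5, 3)
  expect_true(neighborhood_stats(same, 3)$degenerate)
})

test_that("weighted covariance reduces to the plain mean of outer products on symmetric neighborhoods", {
  # all neighbors equidistant from the centroid -> uniform weights
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- cbind(cos(th), sin(th), 0)
  st <- neighborhood_stats(ring, 5, feature_params(m = 4))
  keep <- setdiff(seq_len(nrow(ring)), 5)
  centered <- sweep(ring[keep, ], 2, colMeans(ring))
  C_unif <- crossprod(centered) / length(keep)
  expect_equal(max(abs(st$C - C_unif)), 0, tolerance = 1e-10)
  expect_equal(st$weights, rep(1 / 7, 7), tolerance = 1e-6)
})

test_that("feature classification separates planes from poles and is rigid-invariant", {
  # large plane: interior points overwhelmingly planar
  traj <- pose_sample(0, p = c(0, 0, 0))
  fr <- generate_scan_frame(plane_scene(tilt = 0.25), list(traj), rows = 8, cols = 360)
  lab <- classify_features(fr$image, fr$cloud)
  frac_planar <- mean(lab$label == "planar")
  expect_gt(frac_planar, 0.90)
  expect_lt(mean(lab$label == "edge"), 0.02)
  # thin pole in empty space: predominantly edge
  pole <- list(list(type = "cylinder", base = c(2, 0, -2), axis = c(0, 0, 1),
                    radius = 0.02, height = 6))
  fp <- generate_scan_frame(pole, list(traj), rows = 8, cols = 1800)
  labp <- classify_features(fp$image, fp$cloud)
  expect_gt(mean(labp$label == "edge"), 0.5)
  # labels are invariant under a rigid transform of the organized rows
  rows <- lapply(seq_len(fr$image$rows), function(r) {
    idx <- fr$image$index[r, ]; xyz(fr$cloud)[idx[idx > 0], , drop = FALSE]
  })
  R <- stemscan:::quat_to_rotmat(quat_from_axis_angle(c(1, 2, 3), 0.7))
  rows_rt <- lapply(rows, function(m) m %*% t(R) + rep(c(5, -2, 1), each = nrow(m)))
  l1 <- classify_features(rows, params = feature_params())
  l2 <- classify_features(rows_rt, params = feature_params())
  expect_equal(as.character(l1$label), as.character(l2$label))
  # edge and planar sets are disjoint and bounded by the point count
  expect_lte(sum(l1$label != "none"), nrow(l1))
})

test_that("all-identical points are labelled none", {
  rows <- list(matrix(1, 20, 3))
  lab <- classify_features(rows, params = feature_params())
  expect_true(all(lab$label == "none"))
})

test_that("point-to-line distance matches its projection oracle", {
  expect_equal(point_to_line_distance(c(0.5, 0, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(point_to_line_distance(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 1)
  set.seed(5)
  for (i in 1:20) {
    p <- rnorm(3); a <- rnorm(3); b <- rnorm(3)
    u <- b - a
    proj <- a + sum((p - a) * u) / sum(u^2) * u
    expect_equal(point_to_line_distance(p, a, b), sqrt(sum((p - proj)^2)),
                 tolerance = 1e-12)
  }
  expect_error(point_to_line_distance(c(1, 1, 1), c(0, 0, 0), c(0, 0, 0)),
               "degenerate")
})

test_that("point-to-plane distance matches the implicit-form oracle", {
  expect_equal(point_to_plane_distance(c(0.2, 0.2, 0), c(0, 0, 0),
                                       c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(point_to_plane_distance(c(0, 0, 2), c(0, 0, 0),
                                       c(1, 0, 0), c(0, 1, 0)), 2)
  set.seed(6)
  for (i in 1:20) {
    p <- rnorm(3); a <- rnorm(3); b <- rnorm(3); cc <- rnorm(3)
    n <- pracma_cross(a - b, a - cc)
    d <- -sum(n * a)
    expect_equal(point_to_plane_distance(p, a, b, cc),
                 abs(sum(n * p) + d) / sqrt(sum(n^2)), tolerance = 1e-12)
  }
  expect_error(point_to_plane_distance(c(1, 1, 1), c(0, 0, 0),
                                       c(1, 0, 0), c(2, 0, 0)), "degenerate")
})
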