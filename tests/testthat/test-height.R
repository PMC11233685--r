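vertical_fit <- function(center = c(0, 0), radius = 0.06) {
  structure(list(axis_point = c(center, 1.1), axis_dir = c(0, 0, 1),
                 radius = radius, inlier_count = 100L,
                 inlier_threshold = 0.04, ok = TRUE),
            class = "cylinder_fit")
}

test_that("near-axis filtering equals the point-to-line oracle", {
  on_axis <- point_cloud(rep(0, 5), rep(0, 5), seq(0, 2, 0.5))
  fit <- vertical_fit()
  expect_equal(n_points(filter_near_axis(on_axis, fit, 0.15)), 5)
  far <- point_cloud(0.2, 0, 1)
  expect_equal(n_points(filter_near_axis(far, fit, 0.15)), 0)
  set.seed(61)
  pc <- point_cloud(runif(1000, -0.5, 0.5), runif(1000, -0.5, 0.5),
                    runif(1000, 0, 2.5))
  kept <- filter_near_axis(pc, fit, 0.15)
  oracle <- vapply(seq_len(1000), function(i)
    point_to_line_distance(unlist(xyz(pc)[i, ]), fit$axis_point,
                           fit$axis_point + fit$axis_dir), 0)
  expect_equal(n_points(kept), sum(oracle < 0.15))
  expect_equal(kept$x, pc$x[oracle < 0.15])
  expect_error(filter_near_axis(pc, NULL), "cylinder")
})

test_that("window slicing follows the half-open bottom-up convention", {
  # 60 windows for max z just under 1.7 from z_start 0.5 at d = 0.02
  pc <- point_cloud(c(0, 0), c(0, 0), c(0.9, 1.6999))
  w <- slice_windows(pc)
  expect_equal(nrow(w), 60)
  expect_equal(w$z_lo[1], 0.5)
  # a point exactly on an upper edge counts in the next window
  pe <- point_cloud(0, 0, 0.52)
  we <- slice_windows(pe)
  expect_equal(we$n_points[1], 0L)
  expect_equal(we$n_points[2], 1L)
  # uniform cylinder: every populated window has a ~ b ~ 2r
  cyl <- point_cloud(cylinder_points(6000, r = 0.06, height = 1.2, z0 = 0.5))
  wc <- slice_windows(cyl)
  busy <- wc[wc$n_points > 30, ]
  expect_equal(mean(busy$a), 0.12, tolerance = 0.01)
  expect_equal(mean(busy$b), 0.12, tolerance = 0.01)
  expect_warning(slice_windows(point_cloud(0, 0, 0.2)), "below z_start")
})

test_that("boundary detection requires a persistent run of wide windows", {
  mk <- function(ab) data.frame(window_index = seq_along(ab) - 1L,
                                z_lo = 0.5 + (seq_along(ab) - 1) * 0.02,
                                z_hi = 0.5 + seq_along(ab) * 0.02,
                                a = ab / 2, b = ab / 2,
                                n_points = 50L)
  R <- 0.06; thr <- 4 * R + 0.10
  # all windows exactly at 4R: below threshold, nothing found
  det0 <- detect_boundary(mk(rep(4 * R, 80)), R)
  expect_false(det0$found)
  # stem up to z = 1.80 then persistently wide: boundary within one window
  n_stem <- ceiling((1.80 - 0.5) / 0.02)
  ab <- c(rep(4 * R, n_stem), rep(thr + 0.2, 20))
  det1 <- detect_boundary(mk(ab), R)
  expect_true(det1$found)
  expect_lt(abs(det1$boundary_z - 1.80), 0.02 + 1e-9)
  expect_equal(det1$boundary_z, 0.5 + 0.02 * det1$run_start_window)
  # a 5-window leaf spike at z = 1.2 is ignored (continuity rule)
  spike <- ab
  i0 <- floor((1.2 - 0.5) / 0.02)
  spike[i0:(i0 + 4)] <- thr + 0.2
  det2 <- detect_boundary(mk(spike), R)
  expect_equal(det2$boundary_z, det1$boundary_z)
})

test_that("boundary detection is z-translation equivariant and ignores points above", {
  set.seed(62)
  ab <- c(rep(0.24, 40), rep(0.6, 15), rep(0.24, 5))
  mk <- function(ab) data.frame(window_index = seq_along(ab) - 1L,
                                z_lo = 0.5 + (seq_along(ab) - 1) * 0.02,
                                z_hi = 0.5 + seq_along(ab) * 0.02,
                                a = ab / 2, b = ab / 2, n_points = 50L)
  d0 <- detect_boundary(mk(ab), 0.06)
  # shifting the profile k windows up shifts the boundary by k*d
  k <- 7
  d1 <- detect_boundary(mk(c(rep(0.24, k), ab)), 0.06)
  expect_equal(d1$boundary_z, d0$boundary_z + k * 0.02, tolerance = 1e-12)
  # appending wide windows above the detected run changes nothing
  d2 <- detect_boundary(mk(c(ab, rep(0.8, 30))), 0.06)
  expect_equal(d2$boundary_z, d0$boundary_z)
})

test_that("measure_height recovers a synthetic plant and flags canopyless ones", {
  sp <- single_plant(seed = 63, diameter = 0.14, height = 1.8)
  md <- measure_diameter(sp$cloud, seed = 1)
  mh <- measure_height(sp$cloud, md$fit)
  expect_true(mh$measurable)
  expect_lt(abs(mh$height - 1.8), 0.05)
  # bare stem, no canopy: no wide run exists -> flagged, not an error
  bare <- point_cloud(cylinder_points(4000, r = 0.06, height = 1.8, z0 = 0,
                                      sigma = 0.01, seed = 64))
  attr(bare, "is_normalized") <- TRUE
  mb <- measure_height(bare, vertical_fit())
  expect_false(mb$measurable)
  expect_true(is.na(mb$height))
})

test_that("continuity beats the plain sliding window on a bumpy stem", {
  # stem with a short protrusion (leaf stub) at 1.1 m, true boundary at 1.8 m
  sp <- single_plant(seed = 65, diameter = 0.12, height = 1.8)
  stub_z <- runif(250, 0.88, 0.94)
  stub <- point_cloud(3 + runif(250, 0.06, 0.14) * cos(runif(250, 0, 1)),
                      3 + runif(250, 0.06, 0.14) * sin(runif(250, 0, 1)),
                      stub_z)
  cl <- stemscan:::pc_bind(sp$cloud, stub)
  attr(cl, "is_normalized") <- TRUE
  md <- measure_diameter(cl, seed = 2)
  h_cont <- measure_height(cl, md$fit, height_params(run_length = 10L, min_boundary = 0))$height
  h_plain <- measure_height(cl, md$fit, height_params(run_length = 1L, min_boundary = 0))$height
  expect_lt(h_plain, 1.3)                    # plain detector trips on the stub
  expect_lt(abs(h_cont - 1.8), 0.06)
  expect_lt(abs(h_cont - 1.8), abs(h_plain - 1.8))
})
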