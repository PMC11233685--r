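test_that("SOR removes an isolated point and nothing else from a clean grid", {
  g <- expand.grid(x = seq(0, 1, 0.1), y = seq(0, 1, 0.1))
  pc <- point_cloud(c(g$x, 10), c(g$y, 10), c(rep(0, nrow(g)), 10))
  out <- statistical_outlier_removal(pc)
  expect_equal(attr(out, "removed"), nrow(g) + 1L)
  expect_equal(n_points(out), nrow(g))
  # generous multiplier: output = input
  out2 <- statistical_outlier_removal(point_cloud(g$x, g$y, rep(0, nrow(g))),
                                      std_multiplier = 10)
  expect_equal(n_points(out2), nrow(g))
  # tiny cloud returned unchanged with a warning
  tiny <- point_cloud(1:3, 1:3, 1:3)
  expect_warning(out3 <- statistical_outlier_removal(tiny), "smaller")
  expect_equal(n_points(out3), 3)
})

test_that("SOR removes injected outliers but spares surfaces on the orchard fixture", {
  orch <- generate_orchard(small_orchard_config(seed = 21))
  den <- statistical_outlier_removal(orch$cloud)
  removed <- attr(den, "removed")
  comp <- orch$labels$component
  out_idx <- which(comp == "outlier")
  surf_idx <- which(comp %in% c("ground", "stem", "canopy"))
  expect_gte(mean(out_idx %in% removed), 0.90)
  expect_lte(mean(surf_idx %in% removed), 0.01)
})

test_that("ground fitting recovers flat and undulating terrain", {
  set.seed(31)
  # noiseless flat ground plus a stem: all cell heights at 0
  gx <- runif(8000, 0, 10); gy <- runif(8000, 0, 10)
  ground <- point_cloud(gx, gy, rep(0, 8000))
  stem <- point_cloud(5 + 0.06 * cos(runif(900, 0, 2 * pi)),
                      5 + 0.06 * sin(runif(900, 0, 2 * pi)),
                      runif(900, 0, 1.8))
  g <- fit_ground_surface(stemscan:::pc_bind(ground, stem))
  expect_lt(max(abs(g$heights)), 0.02)
  # sinusoidal terrain, no vegetation: surface RMS < 5 cm
  zz <- 0.15 * sin(2 * pi * gx / 10) * cos(2 * pi * gy / 10)
  gu <- fit_ground_surface(point_cloud(gx, gy, zz))
  xc <- seq(0.5, 9.5, 0.25); grid <- expand.grid(x = xc, y = xc)
  pred <- ground_height_at(gu, grid$x, grid$y)
  truth <- 0.15 * sin(2 * pi * grid$x / 10) * cos(2 * pi * grid$y / 10)
  expect_lt(sqrt(mean((pred - truth)^2)), 0.05)
  # footprint too small
  expect_error(fit_ground_surface(point_cloud(runif(30, 0, 0.3),
                                              runif(30, 0, 0.3),
                                              rep(0, 30))),
               "2 x 2")
})

test_that("elevation normalization subtracts the local ground exactly for flat terrain", {
  set.seed(32)
  pc <- point_cloud(runif(3000, 0, 6), runif(3000, 0, 6), rep(2.5, 3000))
  g <- fit_ground_surface(pc)
  nm <- normalize_elevation(pc, g)
  expect_true(is_normalized(nm))
  expect_lt(max(abs(nm$z)), 1e-6)
  expect_equal(nm$x, pc$x)       # XY untouched
  # re-fitting ground on a normalized cloud is (near) idempotent
  g2 <- fit_ground_surface(nm)
  nm2 <- normalize_elevation(nm, g2)
  expect_lt(max(abs(nm2$z - nm$z)), 1e-6)
})

test_that("normalization leaves most ground points near zero on the orchard fixture", {
  orch <- generate_orchard(small_orchard_config(seed = 22))
  g <- fit_ground_surface(orch$cloud)
  nm <- normalize_elevation(orch$cloud, g)
  gz <- nm$z[orch$labels$component == "ground"]
  expect_gt(mean(abs(gz) < 0.10), 0.95)
})

test_that("RANSAC ground removal strips the plane but spares the stem", {
  set.seed(33)
  n <- 6000
  plane <- point_cloud(runif(n, 0, 8), runif(n, 0, 8), rnorm(n, 0, 0.005))
  stem <- point_cloud(cylinder_points(1500, r = 0.07, height = 1.8, z0 = 0,
                                      center = c(4, 4), seed = 33))
  stem <- stemscan:::pc_subset(stem, which(stem$z > 0.06))
  cl <- stemscan:::pc_bind(plane, stem)
  attr(cl, "is_normalized") <- TRUE
  rg <- ransac_remove_ground(cl, seed = 5)
  expect_false(is.null(rg$plane))
  expect_gte(abs(rg$plane$normal[3]), 0.9)
  # >= 99% of (above-threshold) stem points survive
  survivors <- setdiff(seq_len(n_points(cl)), rg$plane$inlier_indices)
  expect_gte(mean((n + seq_len(n_points(stem))) %in% survivors), 0.99)
  # plane gone
  expect_lt(mean(seq_len(n) %in% survivors), 0.05)
})

test_that("consensus picks the dominant of two parallel planes", {
  set.seed(34)
  p1 <- point_cloud(runif(6000, 0, 5), runif(6000, 0, 5), rnorm(6000, 0, 0.003))
  p2 <- point_cloud(runif(4000, 0, 5), runif(4000, 0, 5), 0.3 + rnorm(4000, 0, 0.003))
  cl <- stemscan:::pc_bind(p1, p2)
  attr(cl, "is_normalized") <- TRUE
  rg <- ransac_remove_ground(cl, seed = 6)
  expect_lt(abs(-rg$plane$offset / rg$plane$normal[3]), 0.05)  # z ~ 0 plane won
})

test_that("a cloud with no ground comes back unchanged with a warning", {
  cl <- point_cloud(cylinder_points(1200, height = 1.8, seed = 35))
  attr(cl, "is_normalized") <- TRUE
  expect_warning(rg <- ransac_remove_ground(cl, seed = 1), "consensus")
  expect_equal(n_points(rg$cloud), 1200)
  expect_null(rg$plane)
})

test_that("preprocessing never increases the point count at any stage", {
  orch <- generate_orchard(small_orchard_config(seed = 23))
  n0 <- n_points(orch$cloud)
  den <- statistical_outlier_removal(orch$cloud)
  expect_lte(n_points(den), n0)
  g <- fit_ground_surface(den)
  nm <- normalize_elevation(den, g)
  expect_equal(n_points(nm), n_points(den))
  rg <- ransac_remove_ground(nm, seed = 2)
  expect_lte(n_points(rg$cloud), n_points(nm))
  # uniform lowest point: per-plant ground-contact z values agree across the
  # plot after normalization (spread bounded by the ground-fit error)
  keep <- setdiff(seq_len(n_points(orch$cloud)), attr(den, "removed"))
  lab <- orch$labels[keep, ]
  zmin <- tapply(nm$z[lab$component == "stem"],
                 lab$plant_id[lab$component == "stem"], min)
  expect_lt(max(zmin) - min(zmin), 0.08)
})
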