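# iterative geometric (Gauss-Newton-style) circle fit, used as the oracle for
# the algebraic fit on noisy data
geometric_circle_fit <- function(pts) {
  f0 <- fit_circle_lsq(pts)
  obj <- function(p) sum((sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) - p[3])^2)
  o <- optim(c(f0$center, f0$radius), obj, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 500))
  list(center = o$par[1:2], radius = o$par[3])
}

test_that("algebraic circle fit is exact on exact data", {
  f <- fit_circle_lsq(rbind(c(1, 0), c(0, 1), c(-1, 0)))
  expect_equal(f$center, c(0, 0), tolerance = 1e-12)
  expect_equal(f$radius, 1, tolerance = 1e-12)
  p <- circle_points(100, center = c(2, 3), r = 0.06)
  f2 <- fit_circle_lsq(p)
  expect_equal(f2$center, c(2, 3), tolerance = 1e-9)
  expect_equal(f2$radius, 0.06, tolerance = 1e-9)
  expect_error(fit_circle_lsq(cbind(1:5, 1:5)), "collinear")
})

test_that("algebraic fit tracks the geometric oracle on noisy circles", {
  p <- circle_points(200, center = c(0.5, -0.2), r = 0.06, sigma = 0.005,
                     seed = 51)
  f <- fit_circle_lsq(p)
  g <- geometric_circle_fit(p)
  expect_lt(abs(f$radius - 0.06), 2e-3)
  expect_lt(abs(f$radius - g$radius), 1e-3)
})

test_that("Hough fit is quantization-accurate and outlier-robust", {
  p <- circle_points(150, center = c(0.2, 0.1), r = 0.06)
  f <- fit_circle_hough(p)
  expect_lt(abs(f$radius - 0.06), 0.002 + 1e-12)           # radius resolution
  set.seed(52)
  out <- cbind(runif(64, -0.2, 0.6), runif(64, -0.3, 0.5)) # 30% gross outliers
  f2 <- fit_circle_hough(rbind(p, out))
  expect_lt(abs(f2$radius - 0.06), 0.004 + 1e-12)          # 2 x resolution
  expect_error(fit_circle_hough(matrix(1, 10, 2)), "identical")
})

test_that("trimmed fit equals the plain fit on clean data and resists outliers", {
  p <- circle_points(120, r = 0.07)
  expect_lt(abs(fit_circle_lts(p)$radius - fit_circle_lsq(p)$radius), 1e-9)
  set.seed(53)
  noisy <- circle_points(200, r = 0.07, sigma = 0.003)
  gross <- cbind(runif(50, -0.5, 0.5), runif(50, -0.5, 0.5))  # 20% far outliers
  both <- rbind(noisy, gross)
  e_lsq <- abs(fit_circle_lsq(both)$radius - 0.07)
  e_lts <- abs(fit_circle_lts(both)$radius - 0.07)
  expect_lt(e_lts, e_lsq / 10)
})

test_that("RANSAC cylinder fit recovers exact and noisy stems", {
  p <- cylinder_points(400, r = 0.06, height = 0.2, z0 = 1.0, seed = 54)
  f <- fit_cylinder_ransac(p, seed = 1)
  expect_true(f$ok)
  expect_lt(abs(f$radius - 0.06), 1e-6)
  expect_gt(abs(f$axis_dir[3]), 0.9999)
  # tilted 8 degrees with sensor noise
  pn <- cylinder_points(2000, r = 0.07, height = 0.2, z0 = 1.0, tilt_deg = 8,
                        tilt_az = 1.0, sigma = 0.02, seed = 55)
  fn <- fit_cylinder_ransac(pn, seed = 2)
  expect_lt(abs(fn$radius - 0.07), 0.005 / 2)
  # too few points flags unmeasurable rather than raising
  expect_false(fit_cylinder_ransac(p[1:30, ], seed = 3)$ok)
})

test_that("leaf-like contamination at 30% only mildly inflates the RANSAC error", {
  errs <- sapply(1:5, function(i) {
    clean <- cylinder_points(1500, r = 0.07, height = 0.2, z0 = 1.0,
                             sigma = 0.02, seed = 60 + i)
    e_clean <- abs(fit_cylinder_ransac(clean, seed = i)$radius - 0.07)
    set.seed(600 + i)
    n_out <- 650
    contam <- cbind(runif(n_out, -0.35, 0.35), runif(n_out, -0.35, 0.35),
                    runif(n_out, 1.0, 1.2))
    e_cont <- abs(fit_cylinder_ransac(rbind(clean, contam), seed = i)$radius - 0.07)
    c(e_clean, e_cont)
  })
  expect_lt(mean(errs[2, ]), 2 * mean(errs[1, ]) + 5e-4)
})

test_that("all fitters agree on a noiseless circle; Hough to its quantization", {
  p2 <- circle_points(120, center = c(0.4, 0.7), r = 0.065)
  p3 <- cbind(p2, 1.1)
  r_lsq <- fit_circle_lsq(p2)$radius
  r_lts <- fit_circle_lts(p2)$radius
  r_r2d <- fit_circle_ransac2d(p2, seed = 1)$radius
  r_cyl <- fit_cylinder_ransac(rbind(p3, cbind(p2, 1.0), cbind(p2, 1.2)),
                               seed = 1)$radius
  expect_lt(abs(r_lts - r_lsq), 1e-6)
  expect_lt(abs(r_r2d - r_lsq), 1e-6)
  expect_lt(abs(r_cyl - r_lsq), 1e-6)
  expect_lt(abs(fit_circle_hough(p2)$radius - r_lsq), 0.002 + 1e-12)
})

test_that("RANSAC radius estimates are unbiased at the sensor noise level", {
  reps <- 60
  errs <- vapply(seq_len(reps), function(i) {
    p <- cylinder_points(600, r = 0.07, height = 0.2, z0 = 1.0, sigma = 0.02,
                         seed = 7000 + i)
    fit_cylinder_ransac(p, max_iters = 500L, seed = i)$radius - 0.07
  }, 0)
  se <- sd(errs) / sqrt(reps)
  expect_lt(abs(mean(errs)), 3 * se + 1e-5)
})

test_that("measure_diameter recovers a full synthetic plant and flags degenerate ones", {
  sp <- single_plant(seed = 56, diameter = 0.14, height = 1.8)
  md <- measure_diameter(sp$cloud, seed = 1)
  expect_true(md$measurable)
  expect_lt(abs(md$diameter - 0.14), 0.005)
  # a 0.9 m plant has an empty band
  short <- point_cloud(cylinder_points(500, r = 0.06, height = 0.9, z0 = 0))
  attr(short, "is_normalized") <- TRUE
  expect_warning(ms <- measure_diameter(short, seed = 1), "empty")
  expect_false(ms$measurable)
  expect_true(is.na(ms$diameter))
})

test_that("robustness ordering on the contaminated band: lsq worst, ransac best", {
  err <- matrix(NA_real_, 3, 4, dimnames = list(NULL, c("lsq", "hough", "lts", "ransac")))
  for (i in 1:3) {
    clean <- cylinder_points(1200, r = 0.07, height = 0.2, z0 = 1.1,
                             sigma = 0.01, seed = 80 + i)
    set.seed(800 + i)
    n_out <- 300                                          # 20% contamination
    contam <- cbind(runif(n_out, -0.3, 0.3), runif(n_out, -0.3, 0.3),
                    runif(n_out, 1.0, 1.2))
    cl <- point_cloud(rbind(clean, contam))
    attr(cl, "is_normalized") <- TRUE
    for (meth in colnames(err)) {
      md <- measure_diameter(cl, method = meth, band = c(1.0, 1.2), seed = i)
      err[i, meth] <- abs(md$diameter - 0.14)
    }
  }
  e <- colMeans(err)
  expect_gte(e["lsq"], max(e["hough"], e["lts"]))
  expect_gte(min(e["hough"], e["lts"]), e["ransac"])
})
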