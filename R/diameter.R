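#' Extract the fixed-height measurement band of a plant
#'
#' The pseudo-stem diameter is measured on the 1.0-1.2 m band above the
#' normalized ground, where the stem is clear of weeds and most leaves. The
#' band is SOR-refiltered; plants with too few band points are flagged
#' unmeasurable instead of raising.
#'
#' @param cloud One plant's normalized [point_cloud()].
#' @param band `c(z_lo, z_hi)`, meters.
#' @param min_points Fewer band points than this flags the plant (default 20).
#' @return The band [point_cloud()] with attribute `measurable` (logical).
#' @export
extract_band <- function(cloud, band = c(1.0, 1.2), min_points = 20L) {
  out <- extract_height_slab(cloud, band)
  if (nrow(out) >= min_points && nrow(out) > 20) {
    # gentle refilter: kill gross strays only. An aggressive multiplier
    # preferentially strips the sparser outer radial tail of the noisy stem
    # surface and biases the fitted diameter low.
    out <- statistical_outlier_removal(out, std_multiplier = 2.5)
  }
  attr(out, "measurable") <- nrow(out) >= min_points
  out
}

#' Algebraic least-squares circle fit
#'
#' The closed-form Kasa fit: minimizes the algebraic residual of
#' `x^2 + y^2 + a x + b y + c`, the linearization of the geometric circle
#' least-squares problem. Fast and exact on noiseless data, but sensitive to
#' outliers and partial arcs.
#'
#' @param pts n x 2 matrix of planar points, meters.
#' @return A `circle_fit`: list with `center`, `radius`, `method`,
#'   `inlier_count`, `residual_rms`.
#' @export
fit_circle_lsq <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) stop("circle fit requires at least 3 points")
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(x, y, 1)
  if (qr(A)$rank < 3) stop("degenerate circle fit: points are collinear")
  b <- x^2 + y^2
  cf <- unname(qr.solve(A, b))
  cx <- cf[1] / 2; cy <- cf[2] / 2
  r2 <- cf[3] + cx^2 + cy^2
  if (r2 <= 0) stop("degenerate circle fit: non-positive squared radius")
  r <- sqrt(r2)
  res <- sqrt((x - cx)^2 + (y - cy)^2) - r
  circle_fit(c(cx, cy), r, "lsq", nrow(pts), sqrt(mean(res^2)))
}

circle_fit <- function(center, radius, method, inlier_count, residual_rms) {
  structure(list(center = as.numeric(center), radius = radius, method = method,
                 inlier_count = as.integer(inlier_count),
                 residual_rms = residual_rms),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("circle_fit [%s]: center (%.4f, %.4f), radius %.4f m, %d inliers, rms %.4g m\n",
              x$method, x$center[1], x$center[2], x$radius, x$inlier_count,
              x$residual_rms))
  invisible(x)
}

#' Hough-transform circle fit
#'
#' Votes in a quantized (cx, cy, r) accumulator spanning the data bounding
#' box padded by the maximum radius; the peak cell wins (ties broken toward
#' the larger vote count, then the smaller radius). Robust to gross outliers
#' at the cost of quantization error.
#'
#' @param pts n x 2 matrix, meters.
#' @param radius_range Search range for the radius, meters.
#' @param center_resolution,radius_resolution Accumulator cell sizes, meters.
#' @param n_angles Votes cast per (point, radius) pair.
#' @return A `circle_fit` (method `"hough"`).
#' @export
fit_circle_hough <- function(pts, radius_range = c(0.03, 0.12),
                             center_resolution = 0.005,
                             radius_resolution = 0.002,
                             n_angles = 64L) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) stop("circle fit requires at least 3 points")
  if (nrow(unique(round(pts, 12))) < 3) stop("degenerate Hough fit: all points identical")
  radii <- seq(radius_range[1], radius_range[2], by = radius_resolution)
  x0 <- min(pts[, 1]) - radius_range[2]; x1 <- max(pts[, 1]) + radius_range[2]
  y0 <- min(pts[, 2]) - radius_range[2]; y1 <- max(pts[, 2]) + radius_range[2]
  nx <- max(1L, as.integer(ceiling((x1 - x0) / center_resolution)))
  ny <- max(1L, as.integer(ceiling((y1 - y0) / center_resolution)))
  ang <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  ca <- cos(ang); sa <- sin(ang)
  best <- NULL
  for (ri in seq_along(radii)) {
    r <- radii[ri]
    cx <- as.vector(outer(pts[, 1], r * ca, `-`))
    cy <- as.vector(outer(pts[, 2], r * sa, `-`))
    ix <- as.integer(floor((cx - x0) / center_resolution))
    iy <- as.integer(floor((cy - y0) / center_resolution))
    ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
    if (!any(ok)) next
    cell <- ix[ok] * ny + iy[ok]
    tb <- tabulate(cell + 1L)
    peak <- which.max(tb)
    votes <- tb[peak]
    if (is.null(best) || votes > best$votes) {
      pix <- (peak - 1L) %/% ny; piy <- (peak - 1L) %% ny
      best <- list(votes = votes, r = r,
                   cx = x0 + (pix + 0.5) * center_resolution,
                   cy = y0 + (piy + 0.5) * center_resolution)
    }
  }
  if (is.null(best)) stop("empty Hough accumulator")
  res <- sqrt((pts[, 1] - best$cx)^2 + (pts[, 2] - best$cy)^2) - best$r
  circle_fit(c(best$cx, best$cy), best$r, "hough", best$votes,
             sqrt(mean(res^2)))
}

#' Least-trimmed-squares circle fit
#'
#' Iterates the algebraic fit, dropping the `trim_fraction` of points with
#' the largest absolute radial residual and refitting the retained set until
#' membership stabilizes. Robust to a minority of gross outliers.
#'
#' @param pts n x 2 matrix, meters.
#' @param trim_fraction Fraction trimmed each round (default 0.25).
#' @param max_iters Iteration cap (default 20).
#' @return A `circle_fit` (method `"lts"`) on the retained set.
#' @export
fit_circle_lts <- function(pts, trim_fraction = 0.25, max_iters = 20L) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < ceiling(3 / (1 - trim_fraction)))
    stop("too few points for the requested trim fraction")
  keep <- seq_len(n)
  n_keep <- max(3L, as.integer(ceiling(n * (1 - trim_fraction))))
  for (it in seq_len(max_iters)) {
    f <- fit_circle_lsq(pts[keep, , drop = FALSE])
    res <- abs(sqrt((pts[, 1] - f$center[1])^2 + (pts[, 2] - f$center[2])^2) - f$radius)
    new_keep <- order(res)[seq_len(n_keep)]
    if (setequal(new_keep, keep)) { keep <- new_keep; break }
    keep <- new_keep
  }
  f <- fit_circle_lsq(pts[keep, , drop = FALSE])
  circle_fit(f$center, f$radius, "lts", length(keep), f$residual_rms)
}

#' RANSAC 2D circle fit
#'
#' Repeatedly fits the circumcircle of random point triples, scores by the
#' count of points within `inlier_threshold` of the circle, and refits the
#' best consensus set with the algebraic least-squares fit.
#'
#' @param pts n x 2 matrix, meters.
#' @param inlier_threshold Radial inlier distance, meters.
#' @param max_iters Iterations.
#' @param seed Integer seed.
#' @return A `circle_fit` (method `"ransac2d"`).
#' @export
fit_circle_ransac2d <- function(pts, inlier_threshold = 0.01,
                                max_iters = 500L, seed = 1L) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("circle fit requires at least 3 points")
  set.seed(seed)
  x <- pts[, 1]; y <- pts[, 2]
  best_in <- integer(0)
  for (it in seq_len(max_iters)) {
    tri <- sample.int(n, 3L)
    cc <- tryCatch(circumcircle(pts[tri, , drop = FALSE]), error = function(e) NULL)
    if (is.null(cc)) next
    res <- abs(sqrt((x - cc$center[1])^2 + (y - cc$center[2])^2) - cc$radius)
    inl <- which(res <= inlier_threshold)
    if (length(inl) > length(best_in)) best_in <- inl
  }
  if (length(best_in) < 3) stop("RANSAC circle: no consensus found")
  f <- fit_circle_lsq(pts[best_in, , drop = FALSE])
  circle_fit(f$center, f$radius, "ransac2d", length(best_in), f$residual_rms)
}

circumcircle <- function(p) {
  ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
  cx <- p[3, 1]; cy <- p[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) stop("collinear triple")
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

#' RANSAC 3D cylinder fit
#'
#' The reference diameter estimator. Stems are near-vertical after
#' normalization, so each iteration perturbs the vertical axis within a cone,
#' projects a random point triple onto the axis-normal plane, hypothesizes
#' the triple's circumcircle as the cylinder cross-section, and scores by the
#' count of points whose distance to the axis is within `inlier_threshold` of
#' the radius. The best hypothesis is refined by geometric least squares
#' (Gauss-Newton via `optim`) on its inliers.
#'
#' @param pts n x 3 matrix of band points, meters.
#' @param inlier_threshold Inlier distance, meters (default 0.04 = 2 sigma of
#'   the sensor noise).
#' @param max_iters Iterations (default 2000).
#' @param seed Integer seed.
#' @param axis_cone_deg Half-angle of the axis search cone around vertical.
#' @param min_inlier_frac Consensus below this fraction flags failure.
#' @param radius_range Admissible hypothesis radii, meters (default
#'   `c(0.03, 0.15)`, the crop prior: pseudo-stem diameters run 10-18 cm).
#'   Keeps the sampler from locking onto leaf-sheath arcs or point clumps.
#' @return A `cylinder_fit`: list with `axis_point`, `axis_dir` (unit, z-up),
#'   `radius`, `inlier_count`, `inlier_threshold`, `ok`; `ok = FALSE` when no
#'   acceptable consensus exists.
#' @export
fit_cylinder_ransac <- function(pts, inlier_threshold = 0.04, max_iters = 2000L,
                                seed = 1L, axis_cone_deg = 30,
                                min_inlier_frac = 0.30,
                                radius_range = c(0.03, 0.15)) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 50) {
    return(structure(list(axis_point = c(NA, NA, NA), axis_dir = c(0, 0, 1),
                          radius = NA_real_, inlier_count = 0L,
                          inlier_threshold = inlier_threshold, ok = FALSE),
                     class = "cylinder_fit"))
  }
  set.seed(seed)
  z_mid <- mean(range(pts[, 3]))
  cone <- axis_cone_deg * pi / 180
  best <- NULL; best_count <- -1L
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  for (it in seq_len(max_iters)) {
    # vertical-prior axis perturbation: half-normal tilt (sd 8 deg, the
    # typical lean of a banana stem), capped at the cone half-angle
    th <- abs(stats::rnorm(1, 0, 8 * pi / 180))
    if (th > cone) next
    ph <- stats::runif(1, 0, 2 * pi)
    v <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    b <- axis_basis(v)
    tri <- sample.int(n, 3L)
    p2 <- cbind((pts[tri, , drop = FALSE] %*% b$u), (pts[tri, , drop = FALSE] %*% b$w))
    cc <- tryCatch(circumcircle(p2), error = function(e) NULL)
    if (is.null(cc) || cc$radius < radius_range[1] || cc$radius > radius_range[2]) next
    pu <- x * b$u[1] + y * b$u[2] + z * b$u[3]
    pw <- x * b$w[1] + y * b$w[2] + z * b$w[3]
    d_ax <- sqrt((pu - cc$center[1])^2 + (pw - cc$center[2])^2)
    res <- abs(d_ax - cc$radius)
    cnt <- sum(res <= inlier_threshold)
    # a pseudo-stem is opaque: returns cannot come from well inside the
    # cylinder. Hypotheses wrapping a sheath annulus around a thinner stem
    # carry many interior points and are rejected.
    interior <- sum(d_ax < cc$radius - inlier_threshold)
    if (interior > max(10, 0.05 * cnt)) next
    if (cnt > best_count) {
      # full-circle support: a real stem surface surrounds its axis, while a
      # cylinder slicing obliquely through stem + sheath arcs only touches a
      # few azimuth sectors. Require inliers in >= 7 of 8 sectors.
      inl <- res <= inlier_threshold
      sect <- floor((atan2(pw[inl] - cc$center[2], pu[inl] - cc$center[1]) + pi) /
                      (2 * pi / 8))
      tab <- tabulate(sect + 1L, 8L)
      if (sum(tab >= max(2, cnt / 40)) < 7L) next
      best_count <- cnt
      best <- list(v = v, b = b, center2 = cc$center, radius = cc$radius)
    }
  }
  if (is.null(best) || best_count < min_inlier_frac * n) {
    return(structure(list(axis_point = c(NA, NA, NA), axis_dir = c(0, 0, 1),
                          radius = NA_real_, inlier_count = 0L,
                          inlier_threshold = inlier_threshold, ok = FALSE),
                     class = "cylinder_fit"))
  }
  # axis point of the best hypothesis at z = z_mid
  ap <- best$center2[1] * best$b$u + best$center2[2] * best$b$w
  ap <- ap + ((z_mid - ap[3]) / best$v[3]) * best$v
  fit <- refine_cylinder(pts, ap, best$v, best$radius, inlier_threshold, z_mid)
  structure(list(axis_point = fit$axis_point, axis_dir = fit$axis_dir,
                 radius = fit$radius, inlier_count = fit$inlier_count,
                 inlier_threshold = inlier_threshold, ok = TRUE),
            class = "cylinder_fit")
}

# geometric least-squares refinement: params (ax, ay, tx, ty, r) with the
# axis point constrained to the z = z_mid plane and direction
# (tx, ty, sqrt(1 - tx^2 - ty^2))
refine_cylinder <- function(pts, axis_point, axis_dir, radius,
                            inlier_threshold, z_mid) {
  dist_to_axis <- function(par) {
    v <- c(par[3], par[4], sqrt(max(1e-8, 1 - par[3]^2 - par[4]^2)))
    a <- c(par[1], par[2], z_mid)
    d <- sweep(pts, 2, a)
    proj <- d %*% v
    sqrt(pmax(0, rowSums(d^2) - proj^2))
  }
  inl <- seq_len(nrow(pts))
  par <- c(axis_point[1] + (z_mid - axis_point[3]) / axis_dir[3] * axis_dir[1],
           axis_point[2] + (z_mid - axis_point[3]) / axis_dir[3] * axis_dir[2],
           axis_dir[1], axis_dir[2])
  for (round in 1:2) {
    res0 <- abs(dist_to_axis(par) - radius)
    inl <- which(res0 <= inlier_threshold)
    if (length(inl) < 10) break
    sub <- pts[inl, , drop = FALSE]
    obj <- function(p) {
      v <- c(p[3], p[4], sqrt(max(1e-8, 1 - p[3]^2 - p[4]^2)))
      a <- c(p[1], p[2], z_mid)
      d <- sweep(sub, 2, a)
      proj <- d %*% v
      dd <- sqrt(pmax(1e-12, rowSums(d^2) - proj^2))
      r <- mean(dd)                       # optimal radius given the axis
      sum((dd - r)^2)
    }
    tilt_max <- 0.5                       # sin(30 deg): stems are near-vertical
    opt <- stats::optim(par, obj, method = "L-BFGS-B",
                        lower = c(par[1] - 0.3, par[2] - 0.3, -tilt_max, -tilt_max),
                        upper = c(par[1] + 0.3, par[2] + 0.3, tilt_max, tilt_max),
                        control = list(maxit = 60, factr = 1e4))
    par <- opt$par
    v <- c(par[3], par[4], sqrt(max(1e-8, 1 - par[3]^2 - par[4]^2)))
    a <- c(par[1], par[2], z_mid)
    d <- sweep(sub, 2, a)
    dd <- sqrt(pmax(0, rowSums(d^2) - (d %*% v)^2))
    radius <- mean(dd)
  }
  v <- c(par[3], par[4], sqrt(max(1e-8, 1 - par[3]^2 - par[4]^2)))
  v <- v / sqrt(sum(v^2))
  list(axis_point = c(par[1], par[2], z_mid), axis_dir = v, radius = radius,
       inlier_count = length(inl))
}

#' @export
print.cylinder_fit <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat("cylinder_fit: no acceptable consensus (plant unmeasurable)\n")
  } else {
    cat(sprintf("cylinder_fit: radius %.4f m (diameter %.4f m), axis tilt %.1f deg, %d inliers\n",
                x$radius, 2 * x$radius,
                acos(min(1, abs(x$axis_dir[3]))) * 180 / pi, x$inlier_count))
  }
  invisible(x)
}

#' Measure one plant's pseudo-stem diameter
#'
#' Extracts the 1.0-1.2 m band, fits the requested model and reports
#' `diameter = 2 r`. The 2D circle methods operate on the band projected
#' onto the plane normal to the RANSAC cylinder axis when available (removing
#' the tilt-induced ellipse distortion), else onto the horizontal plane.
#'
#' @param cloud One plant's normalized [point_cloud()].
#' @param method One of `"ransac"` (3D cylinder, the reference method),
#'   `"lsq"`, `"hough"`, `"lts"`, `"ransac2d"`.
#' @param band Measurement band, meters.
#' @param inlier_threshold RANSAC inlier distance, meters.
#' @param max_iters RANSAC iterations.
#' @param seed Integer seed.
#' @param axis Optional known axis (unit 3-vector) for projecting the 2D
#'   methods.
#' @return List with `diameter` (meters, NA when unmeasurable), `fit` (the
#'   fit record), `measurable`, `method`.
#' @export
measure_diameter <- function(cloud, method = c("ransac", "lsq", "hough", "lts", "ransac2d"),
                             band = c(1.0, 1.2), inlier_threshold = 0.04,
                             max_iters = 2000L, seed = 1L, axis = NULL) {
  method <- match.arg(method)
  bandc <- extract_band(cloud, band)
  if (!attr(bandc, "measurable")) {
    return(list(diameter = NA_real_, fit = NULL, measurable = FALSE, method = method))
  }
  m <- xyz(bandc)
  if (method == "ransac") {
    f <- fit_cylinder_ransac(m, inlier_threshold, max_iters, seed)
    if (!f$ok) return(list(diameter = NA_real_, fit = f, measurable = FALSE, method = method))
    return(list(diameter = 2 * f$radius, fit = f, measurable = TRUE, method = method))
  }
  v <- axis
  if (is.null(v)) v <- c(0, 0, 1)
  b <- axis_basis(v)
  p2 <- cbind(m %*% b$u, m %*% b$w)
  f <- switch(method,
              lsq = fit_circle_lsq(p2),
              hough = fit_circle_hough(p2),
              lts = fit_circle_lts(p2),
              ransac2d = fit_circle_ransac2d(p2, inlier_threshold = inlier_threshold / 2,
                                             seed = seed))
  list(diameter = 2 * f$radius, fit = f, measurable = TRUE, method = method)
}
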