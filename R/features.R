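#' Pose samples and quaternion utilities
#'
#' A pose sample is the sensor pose at one instant: a unit quaternion `q`
#' (rotation body -> world, components `c(w, x, y, z)`) and a translation `p`
#' in meters.
#'
#' @param t Time, seconds.
#' @param q Unit quaternion `c(w, x, y, z)`; normalized on construction.
#' @param p Translation 3-vector, meters.
#' @return A `pose_sample` list.
#' @export
pose_sample <- function(t, q = c(1, 0, 0, 0), p = c(0, 0, 0)) {
  stopifnot(length(q) == 4, length(p) == 3, is.finite(t))
  nq <- sqrt(sum(q^2))
  if (nq < 1e-12) stop("zero quaternion in pose sample")
  structure(list(t = as.numeric(t), q = q / nq, p = as.numeric(p)),
            class = "pose_sample")
}

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Quaternion from axis-angle
#' @param axis Rotation axis (any nonzero 3-vector).
#' @param angle Rotation angle, radians.
#' @return Unit quaternion `c(w, x, y, z)`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

quat_slerp <- function(q0, q1, s) {
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }          # shortest arc
  if (d > 1 - 1e-10) {
    q <- (1 - s) * q0 + s * q1               # nearly parallel: nlerp
    return(q / sqrt(sum(q^2)))
  }
  th <- acos(pmin(1, d))
  (sin((1 - s) * th) * q0 + sin(s * th) * q1) / sin(th)
}

#' Interpolate between two pose samples
#'
#' Spherical linear interpolation (shortest arc) on the rotations and linear
#' interpolation on the translations, at the fractional time
#' `s = (t - p0$t) / (p1$t - p0$t)`. This is the interpolation used to align
#' a 10 Hz LiDAR sweep with higher-rate (e.g. 300 Hz) IMU pose samples.
#'
#' @param p0,p1 [pose_sample()]s with `p0$t < p1$t`.
#' @param t Query time, seconds, within `[p0$t, p1$t]`.
#' @return A [pose_sample()] at time `t`.
#' @export
interpolate_pose <- function(p0, p1, t) {
  if (p0$t >= p1$t) stop("pose interpolation requires p0$t < p1$t")
  if (t < p0$t - 1e-12 || t > p1$t + 1e-12)
    stop(sprintf("query time %g outside pose interval [%g, %g]", t, p0$t, p1$t))
  s <- (t - p0$t) / (p1$t - p0$t)
  s <- min(1, max(0, s))
  pose_sample(t, quat_slerp(p0$q, p1$q, s), (1 - s) * p0$p + s * p1$p)
}

#' Motion-compensate (deskew) a sweeping-LiDAR frame
#'
#' During one 0.1 s sweep the sensor moves, so raw points expressed in the
#' sensor frame at their own acquisition times are mutually inconsistent.
#' Each point is transformed into the world via its time-interpolated pose
#' and then into the sensor frame at the reference time, so the whole frame
#' shares one coordinate system.
#'
#' @param cloud A [point_cloud()] with per-point times in column `t`.
#' @param trajectory List of [pose_sample()]s sorted by time, covering every
#'   point timestamp.
#' @param t_ref Frame reference time (default: time of the first trajectory
#'   sample).
#' @return A deskewed [point_cloud()] of the same size and point order.
#' @export
deskew_points <- function(cloud, trajectory, t_ref = NULL) {
  stopifnot("t" %in% names(cloud))
  tt <- vapply(trajectory, function(p) p$t, 0)
  if (is.unsorted(tt, strictly = TRUE)) stop("trajectory times must be strictly increasing")
  if (is.null(t_ref)) t_ref <- tt[1]
  bad <- which(cloud$t < tt[1] - 1e-12 | cloud$t > tt[length(tt)] + 1e-12)
  if (length(bad))
    stop(sprintf("point %d timestamp %.6f not covered by trajectory [%.6f, %.6f]",
                 bad[1], cloud$t[bad[1]], tt[1], tt[length(tt)]))
  pose_at <- function(ti) {
    i <- findInterval(ti, tt, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(tt) - 1L)
    interpolate_pose(trajectory[[i]], trajectory[[i + 1L]], ti)
  }
  ref <- pose_at(min(max(t_ref, tt[1]), tt[length(tt)]))
  R_ref_t <- t(quat_to_rotmat(ref$q))
  m <- xyz(cloud)
  out <- matrix(NA_real_, nrow(m), 3)
  # group points by identical timestamp (columns share times) for speed
  groups <- split(seq_len(nrow(m)), cloud$t)
  for (g in groups) {
    po <- pose_at(cloud$t[g[1]])
    Rw <- quat_to_rotmat(po$q)
    pw <- m[g, , drop = FALSE] %*% t(Rw) + matrix(po$p, length(g), 3, byrow = TRUE)
    out[g, ] <- sweep(pw, 2, ref$p) %*% t(R_ref_t)
  }
  point_cloud(out[, 1], out[, 2], out[, 3],
              ring = cloud$ring, t = cloud$t,
              intensity = cloud$intensity,
              frame_id = attr(cloud, "frame_id"))
}

#' Feature-extraction parameters
#'
#' @param m Neighborhood half-width in points along a scan row (the
#'   neighborhood spans `2m + 1` cells).
#' @param Et Line (edge) threshold on lambda = lambda1 + lambda2, m^2: points
#'   with lambda below `Et` are edge features. Small lambda means the valid
#'   neighborhood is a spatially tight, isolated cluster (a thin structure
#'   with dropouts around it).
#' @param Pt Plane threshold, m^2: points with lambda above `Pt` are planar
#'   features (a long, continuous spread along the surface). Must satisfy
#'   `Et <= Pt`. Defaults are calibrated for scene ranges of roughly 3-8 m.
#' @param weight_mode `"inverse_distance"` (weights `1/(d_j + eps)`) or
#'   `"gaussian"` (weights `exp(-d_j^2 / (2 sigma_d^2))` with `sigma_d` the
#'   mean neighbor distance); both normalized to sum to 1.
#' @return A `feature_params` list.
#' @export
feature_params <- function(m = 5L, Et = 5e-4, Pt = 1.5e-3,
                           weight_mode = c("inverse_distance", "gaussian")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(m >= 1, Et <= Pt)
  structure(list(m = as.integer(m), Et = Et, Pt = Pt, weight_mode = weight_mode),
            class = "feature_params")
}

#' Distance-weighted neighborhood statistics
#'
#' For the `2m + 1` same-row neighborhood around a scan point, computes the
#' centroid, per-neighbor weights from the distance to that centroid, the
#' weighted covariance matrix (center point excluded from the sum), and its
#' eigenvalues sorted in decreasing order. Weighting down-weights far
#' neighbors so isolated returns and range discontinuities dominate the
#' covariance less.
#'
#' @param pts n x 3 matrix of the scan-row points (only valid returns).
#' @param i Center index into `pts`.
#' @param params A [feature_params()].
#' @return List with `p_mean`, `C` (3 x 3), `eigvals` (descending, clipped at
#'   0), `lam` (= lambda1 + lambda2, m^2), `weights`, and `degenerate`
#'   (TRUE when fewer than 3 distinct points are available).
#' @export
neighborhood_stats <- function(pts, i, params = feature_params()) {
  m <- params$m
  lo <- max(1L, i - m); hi <- min(nrow(pts), i + m)
  nb <- pts[lo:hi, , drop = FALSE]
  distinct <- nrow(unique(round(nb, 12)))
  if (nrow(nb) < 3 || distinct < 3) {
    return(list(p_mean = colMeans(nb), C = matrix(0, 3, 3),
                eigvals = c(0, 0, 0), lam = 0, weights = numeric(0),
                degenerate = TRUE))
  }
  p_mean <- colMeans(nb)
  centered <- sweep(nb, 2, p_mean)
  d <- sqrt(rowSums(centered^2))
  ci <- i - lo + 1L                            # center point excluded from C
  keep <- setdiff(seq_len(nrow(nb)), ci)
  w <- switch(params$weight_mode,
              inverse_distance = 1 / (d[keep] + 1e-6),
              gaussian = {
                s <- mean(d[keep]) + 1e-9
                exp(-d[keep]^2 / (2 * s^2))
              })
  w <- w / sum(w)
  cc <- centered[keep, , drop = FALSE]
  C <- crossprod(cc * sqrt(w))                 # sum_j w_j (p_j - mean)(p_j - mean)^T
  ev <- sort(pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  list(p_mean = p_mean, C = C, eigvals = ev, lam = ev[1] + ev[2],
       weights = w, degenerate = FALSE)
}

#' Classify scan points as edge / planar features
#'
#' Per-point classification on an organized frame: for each valid return the
#' distance-weighted covariance of its same-row neighborhood is decomposed
#' and `lambda = lambda1 + lambda2` thresholded: `lambda < Et` labels the
#' point an edge (line) feature, `lambda > Pt` a planar feature, anything
#' between (or a degenerate neighborhood) is unlabelled.
#'
#' @param x A `range_image` (from [project_to_range_image()]) together with
#'   `cloud`, or a list of per-row point matrices.
#' @param cloud The source [point_cloud()] when `x` is a `range_image`.
#' @param params A [feature_params()].
#' @return A data.frame with `point_index`, `label`
#'   (factor edge/planar/none) and `lambda`; one row per valid return.
#' @export
classify_features <- function(x, cloud = NULL, params = feature_params()) {
  rows <- list()
  if (inherits(x, "range_image")) {
    stopifnot(!is.null(cloud))
    m <- xyz(cloud)
    for (r in seq_len(x$rows)) {
      idx <- x$index[r, ]
      idx <- idx[idx > 0]
      if (length(idx)) rows[[length(rows) + 1L]] <- list(pts = m[idx, , drop = FALSE], idx = idx)
    }
  } else if (is.list(x)) {
    for (r in seq_along(x)) {
      p <- as.matrix(x[[r]])
      if (nrow(p)) rows[[length(rows) + 1L]] <- list(pts = p, idx = rep(NA_integer_, nrow(p)))
    }
  } else stop("x must be a range_image or a list of per-row point matrices")
  out <- lapply(rows, function(rw) {
    n <- nrow(rw$pts)
    lam <- numeric(n); lab <- character(n)
    for (i in seq_len(n)) {
      st <- neighborhood_stats(rw$pts, i, params)
      lam[i] <- st$lam
      lab[i] <- if (st$degenerate) "none"
                else if (st$lam < params$Et) "edge"
                else if (st$lam > params$Pt) "planar"
                else "none"
    }
    data.frame(point_index = rw$idx, label = lab, lambda = lam)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$label <- factor(res$label, levels = c("edge", "planar", "none"))
  res
}

#' Perpendicular distance from a point to a line
#'
#' The residual used for edge-feature scan matching: distance from `p` to the
#' line through map features `a` and `b`, computed as
#' `||(p - a) x (p - b)|| / ||a - b||`.
#'
#' @param p,a,b Numeric 3-vectors (meters).
#' @return Distance in meters.
#' @export
point_to_line_distance <- function(p, a, b) {
  ab <- b - a
  nab <- sqrt(sum(ab^2))
  if (nab < 1e-12) stop("degenerate geometry: line endpoints coincide")
  u <- p - a; v <- p - b
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  sqrt(sum(cr^2)) / nab
}

#' Distance from a point to the plane through three points
#'
#' The residual used for planar-feature scan matching:
#' `|(p - a) . n|` with `n` the unit normal of the plane spanned by
#' `a`, `b`, `c`.
#'
#' @param p,a,b,c Numeric 3-vectors (meters); `a`, `b`, `c` non-collinear.
#' @return Distance in meters.
#' @export
point_to_plane_distance <- function(p, a, b, c) {
  u <- a - b; v <- a - c
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate geometry: plane points are collinear")
  abs(sum((p - a) * n)) / nn
}
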