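#' Statistical outlier removal (SOR)
#'
#' Removes points whose mean distance to their `k` nearest neighbors exceeds
#' the global mean by more than `std_multiplier` standard deviations — the
#' classic denoising pass applied to the reconstructed orchard map before any
#' measurement.
#'
#' @param cloud A [point_cloud()].
#' @param k_neighbors Neighborhood size (default 16).
#' @param std_multiplier Cutoff in standard deviations above the global mean
#'   (default 1.0).
#' @return The filtered [point_cloud()]; the removed row indices are attached
#'   as attribute `removed`.
#' @export
statistical_outlier_removal <- function(cloud, k_neighbors = 16L, std_multiplier = 1.0) {
  n <- nrow(cloud)
  if (n <= k_neighbors) {
    warning("cloud smaller than k_neighbors; returned unchanged")
    attr(cloud, "removed") <- integer(0)
    return(cloud)
  }
  d <- .knn_mean_dist_kd_cpp(cloud$x, cloud$y, cloud$z, as.integer(k_neighbors))
  mu <- mean(d, na.rm = TRUE)
  sdev <- stats::sd(d, na.rm = TRUE)
  keep <- is.na(d) | d <= mu + std_multiplier * sdev
  out <- pc_subset(cloud, which(keep))
  attr(out, "removed") <- which(!keep)
  out
}

#' Ground surface model
#'
#' A rasterized ground elevation surface: per-cell robust low quantile of z
#' followed by iterative neighbor relaxation — a cloth-simulation-like
#' inverted-surface fit that tracks smooth terrain under vegetation without
#' reimplementing the published cloth dynamics.
#'
#' @param cloud A [point_cloud()].
#' @param cell_size Raster cell size, meters (default 0.5).
#' @param rigidity Number of neighbor-relaxation smoothing passes (default 3).
#' @return A `ground_model`: list with `grid_origin`, `cell_size`, `heights`
#'   matrix and `method`.
#' @export
fit_ground_surface <- function(cloud, cell_size = 0.5, rigidity = 3L) {
  m <- xyz(cloud)
  if (nrow(m) == 0) stop("cannot fit ground surface to an empty cloud")
  x0 <- min(m[, 1]); y0 <- min(m[, 2])
  nx <- max(1L, as.integer(ceiling((max(m[, 1]) - x0) / cell_size)))
  ny <- max(1L, as.integer(ceiling((max(m[, 2]) - y0) / cell_size)))
  if (nx < 2 || ny < 2)
    stop("cloud footprint spans fewer than 2 x 2 ground cells; enlarge the cloud or shrink cell_size")
  ix <- pmin(nx, pmax(1L, as.integer(floor((m[, 1] - x0) / cell_size)) + 1L))
  iy <- pmin(ny, pmax(1L, as.integer(floor((m[, 2] - y0) / cell_size)) + 1L))
  dt <- data.table::data.table(ix = ix, iy = iy, z = m[, 3])
  q <- dt[, list(h = stats::quantile(z, 0.05, names = FALSE)), by = c("ix", "iy")]
  H <- matrix(NA_real_, nx, ny)
  H[cbind(q$ix, q$iy)] <- q$h
  # fill empty cells by repeated neighbor means
  for (iter in 1:100) {
    nas <- which(is.na(H), arr.ind = TRUE)
    if (!nrow(nas)) break
    Hn <- neighbor_mean(H)
    fill <- !is.na(Hn[nas])
    if (!any(fill)) break
    H[nas[fill, , drop = FALSE]] <- Hn[nas[fill, , drop = FALSE]]
  }
  if (anyNA(H)) H[is.na(H)] <- stats::median(H, na.rm = TRUE)
  # relaxation: blend towards the neighbor mean, but never rise above the
  # observed low quantile by much (the cloth hugs the lowest returns)
  for (p in seq_len(rigidity)) {
    Hn <- neighbor_mean(H)
    H <- 0.5 * H + 0.5 * Hn
  }
  structure(list(grid_origin = c(x0, y0), cell_size = cell_size,
                 heights = H, method = "robust_grid"),
            class = "ground_model")
}

neighbor_mean <- function(H) {
  nx <- nrow(H); ny <- ncol(H)
  acc <- matrix(0, nx, ny); cnt <- matrix(0, nx, ny)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    src_i <- seq_len(nx) + s[1]; src_j <- seq_len(ny) + s[2]
    oi <- src_i >= 1 & src_i <= nx; oj <- src_j >= 1 & src_j <= ny
    v <- H[src_i[oi], src_j[oj], drop = FALSE]
    ok <- !is.na(v)
    a <- acc[oi, oj, drop = FALSE]; c2 <- cnt[oi, oj, drop = FALSE]
    a[ok] <- a[ok] + v[ok]; c2[ok] <- c2[ok] + 1
    acc[oi, oj] <- a; cnt[oi, oj] <- c2
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Evaluate a ground model at arbitrary XY positions
#'
#' Bilinear interpolation of the elevation raster; positions outside the grid
#' are extrapolated from the nearest cell.
#'
#' @param ground A `ground_model`.
#' @param x,y Coordinate vectors, meters.
#' @return Ground elevations, meters.
#' @export
ground_height_at <- function(ground, x, y) {
  H <- ground$heights
  nx <- nrow(H); ny <- ncol(H)
  gx <- (x - ground$grid_origin[1]) / ground$cell_size - 0.5
  gy <- (y - ground$grid_origin[2]) / ground$cell_size - 0.5
  i0 <- pmin(nx - 1L, pmax(1L, floor(gx) + 1L))
  j0 <- pmin(ny - 1L, pmax(1L, floor(gy) + 1L))
  fx <- pmin(1, pmax(0, gx - (i0 - 1L)))
  fy <- pmin(1, pmax(0, gy - (j0 - 1L)))
  h00 <- H[cbind(i0, j0)]; h10 <- H[cbind(i0 + 1L, j0)]
  h01 <- H[cbind(i0, j0 + 1L)]; h11 <- H[cbind(i0 + 1L, j0 + 1L)]
  (1 - fx) * (1 - fy) * h00 + fx * (1 - fy) * h10 +
    (1 - fx) * fy * h01 + fx * fy * h11
}

#' Elevation normalization
#'
#' Replaces each point's z by its height above the fitted ground surface, so
#' all plants share ground level z = 0 ("a uniform lowest point"). XY are
#' unchanged.
#'
#' @param cloud A [point_cloud()].
#' @param ground A `ground_model` from [fit_ground_surface()].
#' @return The normalized [point_cloud()] (`is_normalized` set).
#' @export
normalize_elevation <- function(cloud, ground) {
  h <- ground_height_at(ground, cloud$x, cloud$y)
  out <- cloud
  out$z <- cloud$z - h
  attr(out, "is_normalized") <- TRUE
  out
}

#' Remove the residual ground plane by RANSAC
#'
#' After normalization the remaining ground returns form a near-horizontal
#' plane around z = 0; the best-consensus plane with |n_z| >= 0.9 is removed.
#' Stem walls can never be claimed because of the horizontality constraint.
#'
#' @param cloud A normalized [point_cloud()].
#' @param inlier_threshold Plane inlier distance, meters (default 0.05).
#' @param max_iters RANSAC iterations (default 1000).
#' @param seed Integer seed for the sampler.
#' @param min_inlier_frac Minimum consensus to accept a plane (default 0.1).
#' @return List with `cloud` (vegetation points) and `plane` (list: unit
#'   `normal`, `offset` with n.x + d = 0, `inlier_indices`,
#'   `inlier_threshold`), or the input unchanged (plane = NULL) when no
#'   acceptable plane exists.
#' @export
ransac_remove_ground <- function(cloud, inlier_threshold = 0.05,
                                 max_iters = 1000L, seed = 1L,
                                 min_inlier_frac = 0.10) {
  if (!is_normalized(cloud))
    warning("ransac_remove_ground expects an elevation-normalized cloud")
  m <- xyz(cloud)
  n <- nrow(m)
  if (n < 3) {
    warning("too few points for plane segmentation; returned unchanged")
    return(list(cloud = cloud, plane = NULL))
  }
  set.seed(seed)
  score_idx <- if (n > 30000L) sample.int(n, 30000L) else seq_len(n)
  ms <- m[score_idx, , drop = FALSE]
  best <- NULL; best_count <- -1L
  for (it in seq_len(max_iters)) {
    tri <- sample.int(n, 3L)
    p1 <- m[tri[1], ]; p2 <- m[tri[2], ]; p3 <- m[tri[3], ]
    u <- p2 - p1; v <- p3 - p1
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) next
    nrm <- nrm / nn
    if (abs(nrm[3]) < 0.9) next                  # must be near-horizontal
    d <- -sum(nrm * p1)
    cnt <- sum(abs(ms %*% nrm + d) <= inlier_threshold)
    if (cnt > best_count) { best_count <- cnt; best <- c(nrm, d) }
  }
  if (is.null(best) || best_count < min_inlier_frac * length(score_idx)) {
    warning("no near-horizontal plane with sufficient consensus; cloud returned unchanged")
    return(list(cloud = cloud, plane = NULL))
  }
  nrm <- best[1:3]; d <- best[4]
  dist_all <- abs(m %*% nrm + d)
  inl <- which(dist_all <= inlier_threshold)
  # refine: least-squares plane on the consensus set (z = a x + b y + c)
  if (length(inl) >= 10) {
    X <- cbind(m[inl, 1], m[inl, 2], 1)
    cf <- tryCatch(qr.solve(X, m[inl, 3]), error = function(e) NULL)
    if (!is.null(cf)) {
      nrm2 <- c(-cf[1], -cf[2], 1); nrm2 <- nrm2 / sqrt(sum(nrm2^2))
      if (abs(nrm2[3]) >= 0.9) {
        d2 <- -cf[3] * nrm2[3]
        dist2 <- abs(m %*% nrm2 + d2)
        inl2 <- which(dist2 <= inlier_threshold)
        if (length(inl2) >= length(inl)) { nrm <- nrm2; d <- d2; inl <- inl2 }
      }
    }
  }
  veg <- pc_subset(cloud, setdiff(seq_len(n), inl))
  plane <- list(normal = nrm, offset = d, inlier_indices = inl,
                inlier_threshold = inlier_threshold)
  list(cloud = veg, plane = plane)
}

#' Full preprocessing pass
#'
#' SOR denoising, ground-surface fit, elevation normalization and RANSAC
#' ground removal, with an optional programmatic crop of the target area.
#'
#' @param cloud Raw [point_cloud()].
#' @param crop Optional `c(xmin, xmax, ymin, ymax)` crop, meters.
#' @param sor_k,sor_mult SOR parameters.
#' @param cell_size,rigidity Ground-surface parameters.
#' @param plane_threshold RANSAC ground-removal inlier threshold, meters.
#' @param seed Seed for the plane RANSAC.
#' @return List with `cloud` (vegetation, normalized), `ground`
#'   (`ground_model`), `plane`, and `kept` — the row indices of the returned
#'   points in the input cloud.
#' @export
preprocess_cloud <- function(cloud, crop = NULL, sor_k = 16L, sor_mult = 1.0,
                             cell_size = 0.5, rigidity = 3L,
                             plane_threshold = 0.05, seed = 1L) {
  idx <- seq_len(nrow(cloud))
  if (!is.null(crop)) {
    keep <- cloud$x >= crop[1] & cloud$x <= crop[2] &
      cloud$y >= crop[3] & cloud$y <= crop[4]
    cloud <- pc_subset(cloud, which(keep))
    idx <- idx[keep]
  }
  den <- statistical_outlier_removal(cloud, sor_k, sor_mult)
  removed <- attr(den, "removed")
  if (length(removed)) idx <- idx[-removed]
  ground <- fit_ground_surface(den, cell_size, rigidity)
  norm <- normalize_elevation(den, ground)
  rg <- ransac_remove_ground(norm, inlier_threshold = plane_threshold, seed = seed)
  kept_local <- if (is.null(rg$plane)) seq_len(nrow(norm))
                else setdiff(seq_len(nrow(norm)), rg$plane$inlier_indices)
  list(cloud = rg$cloud, ground = ground, plane = rg$plane, kept = idx[kept_local])
}
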