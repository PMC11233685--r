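# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays well inside its budget.

# a small but full-featured orchard (plants + sheaths + canopy + ground)
small_orchard_config <- function(seed = 42, ...) {
  orchard_config(n_plants = 8, plot_size = 14, seed = seed, ...)
}

# noisy points on a tilted tapered cylinder, returned as a matrix
cylinder_points <- function(n = 2000, r = 0.06, height = 0.2, z0 = 1.0,
                            tilt_deg = 0, tilt_az = 0, sigma = 0,
                            center = c(0, 0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tilt <- tilt_deg * pi / 180
  v <- c(sin(tilt) * cos(tilt_az), sin(tilt) * sin(tilt_az), cos(tilt))
  b <- stemscan:::axis_basis(v)
  s <- stats::runif(n, 0, height / v[3])
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  pts <- outer(s, v) + outer(rr * cos(th), b$u) + outer(rr * sin(th), b$w)
  pts[, 1] <- pts[, 1] + center[1]
  pts[, 2] <- pts[, 2] + center[2]
  pts[, 3] <- pts[, 3] + z0
  pts
}

# exact points on a 2D circle
circle_points <- function(n, center = c(0, 0), r = 0.06, sigma = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  rr <- r + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
}

# one synthetic plant (stem + canopy) in the normalized frame, plus truth
single_plant <- function(seed = 1, diameter = 0.14, height = 1.8,
                         tilt_deg = 4, point_density = 4000) {
  set.seed(seed)
  cfg <- orchard_config(n_plants = 1, plot_size = 6, point_density = point_density,
                        seed = seed)
  tilt <- tilt_deg * pi / 180
  az <- stats::runif(1, 0, 2 * pi)
  truth <- list(plant_id = 1L, base_xy = c(3, 3),
                axis_dir = c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt)),
                diameter_at_band = diameter, height = height, crown_z = height)
  stem <- generate_stem(truth, cfg)
  can <- generate_canopy(truth, cfg)
  cloud <- stemscan:::pc_bind(stem, can)
  attr(cloud, "is_normalized") <- TRUE
  list(cloud = cloud, truth = truth, cfg = cfg)
}

# organized frame of a large tilted plane (for feature/deskew tests)
plane_scene <- function(tilt = 0.2) {
  list(list(type = "plane", point = c(0, 0, -1.5),
            normal = c(tilt, 0, 1) / sqrt(1 + tilt^2)))
}

# quadratic-time union-find clustering oracle
brute_force_cluster <- function(m, eps) {
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  D <- as.matrix(stats::dist(m))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] <= eps) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
  vapply(seq_len(n), find, 0L)
}

# canonical form of a partition: map labels to first-occurrence order
canonical_partition <- function(lab) {
  u <- unique(lab)
  match(lab, u)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}
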