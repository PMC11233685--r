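#' Synthetic orchard configuration
#'
#' The generator emulates a mobile-LiDAR scan of a densely planted banana
#' stand: ~30 x 30 m, ~43 plants, pseudo-stem diameters 10-18 cm, radial
#' surface noise matching a +/-2 cm sensor (interpreted as 1 sigma),
#' peeling leaf sheaths around the stems, a petiole "throat" above the
#' stem apex, large drooping leaves, undulating ground with weed clutter,
#' and a sprinkle of gross outliers.
#'
#' @param n_plants Number of plants (default 43).
#' @param plot_size Side of the square plot, meters.
#' @param min_spacing Minimum plant-to-plant distance, meters.
#' @param stem_diameter_range True diameter (at the 1.0-1.2 m band), meters.
#' @param stem_height_range True pseudo-stem height (ground to first leaf
#'   insertion), meters.
#' @param stem_tilt_max Maximum stem tilt from vertical, degrees.
#' @param taper Fractional radius decrease per meter along the stem.
#' @param leaf_count_range Leaves per plant.
#' @param noise_sigma Gaussian surface noise, meters (1 sigma).
#' @param point_density Stem surface sampling density, points / m^2.
#' @param canopy_density Leaf surface density, points / m^2.
#' @param ground_density Ground density, points / m^2, or `NULL` to balance
#'   the ground point count against the vegetation count (a global SOR pass
#'   behaves sensibly only when the ground is not a sparse minority mode).
#' @param ground_amplitude Terrain undulation amplitude, meters.
#' @param outlier_fraction Fraction of gross outliers added.
#' @param weed_tufts Number of weed tufts below 0.5 m, or `NULL` for one per
#'   25 m^2 of plot.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @param occlusion_arc Optional angular dropout: width (radians) of a random
#'   azimuthal sector removed from each stem, 0 to disable (default).
#' @return An `orchard_config` list.
#' @export
orchard_config <- function(n_plants = 43L,
                           plot_size = 30,
                           min_spacing = 2.5,
                           stem_diameter_range = c(0.10, 0.18),
                           stem_height_range = c(1.2, 2.4),
                           stem_tilt_max = 8,
                           taper = 0.05,
                           leaf_count_range = c(5L, 9L),
                           noise_sigma = 0.02,
                           point_density = 4000,
                           canopy_density = 800,
                           ground_density = NULL,
                           ground_amplitude = 0.15,
                           outlier_fraction = 0.005,
                           weed_tufts = NULL,
                           seed = 1L,
                           occlusion_arc = 0) {
  stopifnot(stem_diameter_range[1] <= stem_diameter_range[2],
            stem_height_range[1] <= stem_height_range[2],
            noise_sigma >= 0, point_density > 0,
            leaf_count_range[1] <= leaf_count_range[2])
  if (n_plants * pi * min_spacing^2 / 4 > plot_size^2)
    stop("configuration infeasible: n_plants discs of min_spacing do not fit the plot")
  structure(list(n_plants = as.integer(n_plants), plot_size = plot_size,
                 min_spacing = min_spacing,
                 stem_diameter_range = stem_diameter_range,
                 stem_height_range = stem_height_range,
                 stem_tilt_max = stem_tilt_max, taper = taper,
                 leaf_count_range = leaf_count_range,
                 noise_sigma = noise_sigma, point_density = point_density,
                 canopy_density = canopy_density,
                 ground_density = ground_density,
                 ground_amplitude = ground_amplitude,
                 outlier_fraction = outlier_fraction,
                 weed_tufts = if (!is.null(weed_tufts)) as.integer(weed_tufts),
                 seed = as.integer(seed), occlusion_arc = occlusion_arc),
            class = "orchard_config")
}

# orthonormal basis perpendicular to a unit axis
axis_basis <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(a[2] * v[3] - a[3] * v[2],
         a[3] * v[1] - a[1] * v[3],
         a[1] * v[2] - a[2] * v[1])
  u <- u / sqrt(sum(u^2))
  w <- c(v[2] * u[3] - v[3] * u[2],
         v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  list(u = u, w = w)
}

#' Draw the deterministic layout (truths and shape parameters) of an orchard
#'
#' Separated from point sampling so that the same seed yields the same plant
#' geometry at any sampling density. Plants are placed by dart-throwing
#' Poisson-disk sampling at `min_spacing`.
#'
#' @param cfg An [orchard_config()].
#' @return List with `truths` (data.frame: plant_id, base_x, base_y, axis
#'   direction, diameter_m, height_m, crown_z) and per-plant shape details.
#' @keywords internal
orchard_layout <- function(cfg) {
  set.seed(cfg$seed)
  margin <- 1.0
  lo <- margin; hi <- cfg$plot_size - margin
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < cfg$n_plants) {
    if (tries > 4000L * cfg$n_plants)
      stop("plant placement infeasible after bounded retries; reduce n_plants or min_spacing")
    x <- stats::runif(1, lo, hi); y <- stats::runif(1, lo, hi)
    tries <- tries + 1L
    if (!length(xs) || min((xs - x)^2 + (ys - y)^2) >= cfg$min_spacing^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  n <- cfg$n_plants
  diam <- stats::runif(n, cfg$stem_diameter_range[1], cfg$stem_diameter_range[2])
  height <- stats::runif(n, cfg$stem_height_range[1], cfg$stem_height_range[2])
  tilt <- stats::runif(n, 0, cfg$stem_tilt_max) * pi / 180
  tilt_az <- stats::runif(n, 0, 2 * pi)
  axis <- cbind(sin(tilt) * cos(tilt_az), sin(tilt) * sin(tilt_az), cos(tilt))
  leaves_n <- sample(seq(cfg$leaf_count_range[1], cfg$leaf_count_range[2]),
                     n, replace = TRUE)
  plants <- vector("list", n)
  for (i in seq_len(n)) {
    nl <- leaves_n[i]
    ns <- sample(3:5, 1)
    plants[[i]] <- list(
      # leaves: azimuth, initial elevation (shallow: petioles flare out at the
      # throat almost horizontally), length, half-width, end height
      leaf_az = stats::runif(nl, 0, 2 * pi),
      leaf_el = stats::runif(nl, 10, 25) * pi / 180,
      leaf_len = stats::runif(nl, 0.9, 1.4),
      leaf_hw = stats::runif(nl, 0.10, 0.15),
      # peeling dead sheaths crossing the 1.0-1.2 m slab; azimuths spread
      # phyllotactically so the slab footprint widens in both axes
      sheath_az = stats::runif(1, 0, 2 * pi) +
        (seq_len(ns) - 1) * 2 * pi / ns + stats::runif(ns, -0.4, 0.4),
      sheath_zatt = pmin(stats::runif(ns, 1.12, 1.22), height[i]),
      sheath_slope = stats::runif(ns, 0.6, 0.9),
      sheath_width = stats::runif(ns, 0.5, 0.7),
      # petiole bundle above the insertion point
      throat_len = stats::runif(1, 0.4, 0.7),
      occl_az = stats::runif(1, 0, 2 * pi))
  }
  # smooth low-frequency terrain: sum of sinusoids, scaled to the amplitude
  gx <- stats::runif(3, 0.5, 1.5) * 2 * pi / cfg$plot_size
  gy <- stats::runif(3, 0.5, 1.5) * 2 * pi / cfg$plot_size
  gph <- stats::runif(6, 0, 2 * pi)
  gw <- stats::runif(3, 0.5, 1)
  ground_fun <- function(x, y) {
    s <- 0
    for (k in 1:3) s <- s + gw[k] * sin(gx[k] * x + gph[k]) * sin(gy[k] * y + gph[k + 3])
    cfg$ground_amplitude * s / sum(gw)
  }
  truths <- data.frame(plant_id = seq_len(n), base_x = xs, base_y = ys,
                       axis_x = axis[, 1], axis_y = axis[, 2], axis_z = axis[, 3],
                       diameter_m = diam, height_m = height, crown_z = height)
  list(truths = truths, plants = plants, ground_fun = ground_fun,
       leaves_n = leaves_n)
}

truth_row <- function(truths, i) {
  list(plant_id = truths$plant_id[i],
       base_xy = c(truths$base_x[i], truths$base_y[i]),
       axis_dir = c(truths$axis_x[i], truths$axis_y[i], truths$axis_z[i]),
       diameter_at_band = truths$diameter_m[i],
       height = truths$height_m[i],
       crown_z = truths$crown_z[i])
}

#' Sample points on one pseudo-stem
#'
#' A tilted, linearly tapered cylinder from the ground to the first-leaf
#' insertion height, with Gaussian radial surface noise. The drawn diameter
#' is the true diameter at the middle of the 1.0-1.2 m measurement band.
#'
#' @param truth A single-plant truth as produced by [orchard_layout()]
#'   (list with `base_xy`, `axis_dir`, `diameter_at_band`, `height`).
#' @param cfg An [orchard_config()].
#' @param base_z Ground elevation at the stem base (default 0).
#' @return A [point_cloud()] of stem surface points.
#' @export
generate_stem <- function(truth, cfg, base_z = 0) {
  v <- truth$axis_dir / sqrt(sum(truth$axis_dir^2))
  L <- truth$height / v[3]                      # axis length to reach height in z
  r_band <- truth$diameter_at_band / 2
  s_band <- min(1.1, truth$height) / v[3]
  area <- 2 * pi * r_band * L
  n <- max(8L, as.integer(round(area * cfg$point_density)))
  s <- stats::runif(n, 0, L)
  th <- stats::runif(n, 0, 2 * pi)
  if (cfg$occlusion_arc > 0) {
    # angular dropout: remove a sector (occluded side of the stem)
    keep <- ((th - truth$occl_az %||% 0) %% (2 * pi)) > cfg$occlusion_arc
    s <- s[keep]; th <- th[keep]; n <- length(s)
  }
  r <- r_band * (1 - cfg$taper * (s - s_band)) + stats::rnorm(n, 0, cfg$noise_sigma)
  b <- axis_basis(v)
  base <- c(truth$base_xy, base_z)
  pts <- matrix(base, n, 3, byrow = TRUE) +
    outer(s, v) + outer(r * cos(th), b$u) + outer(r * sin(th), b$w)
  point_cloud(pts)
}

#' Sample the canopy of one plant
#'
#' Canopy here means everything leafy: the petiole bundle ("throat") rising
#' from the first-leaf insertion point, the large drooping leaf blades, and
#' the peeling dead leaf sheaths that flare off the lower stem and cross the
#' 1.0-1.2 m slab. The throat and leaf bases widen the horizontal footprint
#' abruptly above the true height (the signal the continuity sliding window
#' detects), while the sheaths give slab clusters the footprint width the
#' plant-segmentation threshold expects.
#'
#' @param truth Single-plant truth (see [generate_stem()]).
#' @param cfg An [orchard_config()].
#' @param shape Per-plant shape parameters from [orchard_layout()]; a
#'   deterministic default is drawn if omitted.
#' @param base_z Ground elevation at the stem base.
#' @return A [point_cloud()]; empty when the plant has zero leaves.
#' @export
generate_canopy <- function(truth, cfg, shape = NULL, base_z = 0) {
  if (is.null(shape)) {
    nl <- max(0L, as.integer(round(mean(cfg$leaf_count_range))))
    if (nl == 0)
      return(point_cloud(numeric(0), numeric(0), numeric(0)))
    shape <- list(leaf_az = seq(0, 2 * pi, length.out = nl + 1)[-1],
                  leaf_el = rep(18 * pi / 180, nl),
                  leaf_len = rep(1.1, nl), leaf_hw = rep(0.12, nl),
                  sheath_az = c(0, 2.1, 4.2), sheath_zatt = c(1.14, 1.17, 1.20),
                  sheath_slope = c(0.8, 0.85, 0.9),
                  sheath_width = c(0.6, 0.6, 0.6),
                  throat_len = 0.5)
  }
  nl <- length(shape$leaf_az)
  if (nl == 0)   # a leafless plant carries no throat and no dead sheaths
    return(point_cloud(numeric(0), numeric(0), numeric(0)))
  v <- truth$axis_dir / sqrt(sum(truth$axis_dir^2))
  base <- c(truth$base_xy, base_z)
  crown_s <- truth$height / v[3]
  apex <- base + crown_s * v                     # first-leaf insertion point
  r_band <- truth$diameter_at_band / 2
  r_top <- max(0.02, r_band * (1 - cfg$taper * (crown_s - min(1.1, truth$height) / v[3])))
  sg <- cfg$noise_sigma
  parts <- list()

  ## throat: petioles and the rolled emerging leaf above the insertion point
  tl <- shape$throat_len %||% 0.5
  n_th <- max(0L, as.integer(round(2 * pi * 0.15 * tl * cfg$point_density)))
  if (nl > 0 && n_th > 0) {
    zt <- stats::runif(n_th, 0, tl)
    tht <- stats::runif(n_th, 0, 2 * pi)
    # radial spread widens immediately above the insertion: the footprint jump
    # (absolute scale, so it clears 4R + dw for even the largest stems)
    rad <- stats::runif(n_th, 0.08, 0.18) + abs(stats::rnorm(n_th, 0, sg))
    pts <- matrix(apex, n_th, 3, byrow = TRUE) +
      outer(zt, c(0, 0, 1)) + cbind(rad * cos(tht), rad * sin(tht), 0)
    parts[[length(parts) + 1L]] <- pts
  }

  ## leaf blades: drooping ribbons from the apex
  for (k in seq_len(nl)) {
    az <- shape$leaf_az[k]; el <- shape$leaf_el[k]
    Lk <- shape$leaf_len[k]; hw <- shape$leaf_hw[k]
    n_k <- max(0L, as.integer(round(2 * hw * Lk * cfg$canopy_density)))
    if (n_k == 0) next
    s <- stats::runif(n_k, 0.05, Lk)
    lat <- stats::runif(n_k, -hw, hw) * pmin(1, s / (0.3 * Lk))
    # midrib: rises at el then droops; tip never falls below ~1.25 m
    z_end <- max(1.25, truth$height - 0.45)
    c_d <- (truth$height + Lk * sin(el) - z_end) / Lk^2
    dir_h <- c(cos(az), sin(az), 0)
    lat_h <- c(-sin(az), cos(az), 0)
    zs <- apex[3] + s * sin(el) - c_d * s^2 + stats::rnorm(n_k, 0, sg)
    pts <- matrix(c(apex[1], apex[2], 0), n_k, 3, byrow = TRUE) +
      outer(r_top + s * cos(el), dir_h) + outer(lat, lat_h) +
      cbind(0, 0, zs)
    parts[[length(parts) + 1L]] <- pts
  }

  ## peeling sheaths: attached just below the slab top, flaring outward on a
  ## continuous ramp so the slab cluster stays Euclidean-connected while its
  ## footprint width K grows well past the bare stem's
  for (k in seq_along(shape$sheath_az)) {
    z_att <- shape$sheath_zatt[k]
    if (z_att > truth$height + 0.05) next
    slope <- shape$sheath_slope[k]
    wid <- shape$sheath_width[k]
    z_lo <- z_att - 0.5
    # area ~ arc length (~ wid x 0.3 m radius) x ~0.55 m slant length; dead
    # sheaths return far sparser than the living stem surface
    n_k <- max(0L, as.integer(round(0.18 * (wid / 0.6) * cfg$point_density * 0.2)))
    if (n_k == 0) next
    zz <- stats::runif(n_k, z_lo, z_att)
    aa <- shape$sheath_az[k] + stats::runif(n_k, -wid / 2, wid / 2)
    # dead sheath bases stand off the stem at a 0.15 m plateau and flare
    # gently to the cap further down. The plateau keeps the sheath outside
    # the W = 0.15 m height-measurement tube for every stem radius, while
    # the dense plateau and stem surfaces still provide abundant point pairs
    # within the Te = 0.15 m linking distance, so slab clusters stay
    # Euclidean-connected.
    dz <- z_att - zz
    delta <- ifelse(dz < 0.18, 0.15,
                    pmin(0.30, 0.15 + slope * (dz - 0.18))) +
      stats::rnorm(n_k, 0, sg)
    # sheath sits around the local stem axis position
    s_ax <- zz / v[3]
    ax_pt <- matrix(base, n_k, 3, byrow = TRUE) + outer(s_ax, v)
    b <- axis_basis(v)
    rr <- r_band * (1 - cfg$taper * (s_ax - min(1.1, truth$height) / v[3])) + delta
    pts <- ax_pt + outer(rr * cos(aa), b$u) + outer(rr * sin(aa), b$w)
    parts[[length(parts) + 1L]] <- pts
  }
  if (!length(parts))
    return(point_cloud(numeric(0), numeric(0), numeric(0)))
  m <- do.call(rbind, parts)
  point_cloud(m)
}

#' Generate a labelled synthetic orchard
#'
#' Undulating ground, Poisson-disk-placed plants (stem + canopy), sparse weed
#' clutter below 0.5 m and uniform gross outliers. Deterministic given the
#' config seed; the same seed yields the same layout at any point density.
#'
#' @param cfg An [orchard_config()].
#' @return List with `cloud` (a [point_cloud()]), `truths` (one row per
#'   plant: plant_id, base_x, base_y, diameter_m, height_m, ...), and
#'   `labels` (data.frame aligned with `cloud`: `component` in ground / stem
#'   / canopy / weed / outlier, and `plant_id`, 0 for unowned points).
#' @export
generate_orchard <- function(cfg) {
  lay <- orchard_layout(cfg)
  set.seed(cfg$seed + 500009L)                  # independent sampling stream
  parts <- list(); comp <- list(); pid <- list()
  push <- function(pc, component, plant_id) {
    if (nrow(pc) == 0) return()
    k <- length(parts) + 1L
    parts[[k]] <<- pc
    comp[[k]] <<- rep(component, nrow(pc))
    pid[[k]] <<- rep(plant_id, nrow(pc))
  }
  gf <- lay$ground_fun
  for (i in seq_len(cfg$n_plants)) {
    tr <- truth_row(lay$truths, i)
    bz <- gf(tr$base_xy[1], tr$base_xy[2])
    push(generate_stem(tr, cfg, base_z = bz), "stem", i)
    push(generate_canopy(tr, cfg, shape = lay$plants[[i]], base_z = bz), "canopy", i)
  }
  n_veg <- sum(vapply(parts, nrow, 0L))
  ## ground: density balanced against vegetation unless configured
  area <- cfg$plot_size^2
  gd <- cfg$ground_density %||% max(50, n_veg / area)
  n_g <- as.integer(round(gd * area))
  gx <- stats::runif(n_g, 0, cfg$plot_size)
  gy <- stats::runif(n_g, 0, cfg$plot_size)
  gz <- mapply(gf, gx, gy) + stats::rnorm(n_g, 0, cfg$noise_sigma)
  push(point_cloud(gx, gy, gz), "ground", 0L)
  ## weed tufts below 0.5 m
  n_tufts <- cfg$weed_tufts %||% max(1L, as.integer(round(area / 25)))
  for (k in seq_len(n_tufts)) {
    cx <- stats::runif(1, 0, cfg$plot_size); cy <- stats::runif(1, 0, cfg$plot_size)
    nw <- as.integer(stats::runif(1, 40, 120))
    wx <- cx + stats::rnorm(nw, 0, 0.12)
    wy <- cy + stats::rnorm(nw, 0, 0.12)
    wz <- mapply(gf, wx, wy) + stats::runif(nw, 0.02, 0.45)
    push(point_cloud(wx, wy, wz), "weed", 0L)
  }
  ## uniform outliers
  n_total <- sum(vapply(parts, nrow, 0L))
  n_out <- as.integer(round(cfg$outlier_fraction * n_total))
  if (n_out > 0) {
    zmax <- max(lay$truths$height_m) + 1.0
    ox <- stats::runif(n_out, 0, cfg$plot_size)
    oy <- stats::runif(n_out, 0, cfg$plot_size)
    oz <- stats::runif(n_out, -0.3, zmax)
    push(point_cloud(ox, oy, oz), "outlier", 0L)
  }
  cloud <- do.call(pc_bind, parts)
  attr(cloud, "frame_id") <- sprintf("synthetic-orchard-seed-%d", cfg$seed)
  list(cloud = cloud,
       truths = lay$truths,
       labels = data.frame(component = unlist(comp), plant_id = unlist(pid)),
       ground_fun = gf)
}

#' Ray-cast one organized scan frame over analytic primitives
#'
#' Simulates one 0.1 s sweep of a 16-beam scanner (rows at elevations -15 to
#' +15 degrees) moving along a pose trajectory. Each azimuth column gets a
#' timestamp linear in azimuth; rays are cast in the sensor pose interpolated
#' at that time, so a moving sensor yields a motion-skewed frame (the fixture
#' for deskew and feature-extraction tests). Points are returned in the
#' sensor frame at their own acquisition times, as a real device reports them.
#'
#' @param scene List of primitives: `list(type = "plane", point =, normal =)`
#'   or `list(type = "cylinder", base =, axis =, radius =, height =)`.
#' @param trajectory List of [pose_sample()]s covering `[t0, t0 + 0.1]`; a
#'   single pose is treated as static.
#' @param rows,cols Frame resolution.
#' @param noise_sigma Range noise, meters.
#' @param max_range Maximum usable range, meters.
#' @return List with `cloud` (a [point_cloud()] with `ring` and `t`) and
#'   `image` (the frame re-projected with [project_to_range_image()]).
#' @export
generate_scan_frame <- function(scene, trajectory, rows = 16L, cols = 1800L,
                                noise_sigma = 0, max_range = 80) {
  if (inherits(trajectory, "pose_sample")) trajectory <- list(trajectory)
  tt <- vapply(trajectory, function(p) p$t, 0)
  t0 <- tt[1]
  period <- 0.1
  elev <- seq(-15, 15, length.out = rows) * pi / 180
  out_x <- numeric(0); out_y <- numeric(0); out_z <- numeric(0)
  out_ring <- integer(0); out_t <- numeric(0)
  for (j in seq_len(cols)) {
    tj <- t0 + period * (j - 1) / cols
    po <- if (length(trajectory) == 1L) trajectory[[1]] else {
      i <- findInterval(tj, tt, rightmost.closed = TRUE)
      i <- min(max(i, 1L), length(tt) - 1L)
      interpolate_pose(trajectory[[i]], trajectory[[i + 1L]], min(tj, tt[length(tt)]))
    }
    Rw <- quat_to_rotmat(po$q)
    az <- 2 * pi * (j - 1) / cols
    for (r in seq_len(rows)) {
      d_local <- c(cos(elev[r]) * cos(az), cos(elev[r]) * sin(az), sin(elev[r]))
      d <- as.vector(Rw %*% d_local)
      o <- po$p
      best <- Inf
      for (pr in scene) {
        if (pr$type == "plane") {
          dn <- sum(d * pr$normal)
          if (abs(dn) < 1e-9) next
          tq <- sum((pr$point - o) * pr$normal) / dn
          if (tq > 1e-6 && tq < best) best <- tq
        } else if (pr$type == "cylinder") {
          v <- pr$axis / sqrt(sum(pr$axis^2))
          w0 <- o - pr$base
          dp <- d - sum(d * v) * v
          wp <- w0 - sum(w0 * v) * v
          A <- sum(dp^2); B <- 2 * sum(dp * wp); C <- sum(wp^2) - pr$radius^2
          if (A < 1e-12) next
          disc <- B^2 - 4 * A * C
          if (disc < 0) next
          for (tq in c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))) {
            if (tq <= 1e-6 || tq >= best) next
            hit_s <- sum((o + tq * d - pr$base) * v)
            if (!is.null(pr$height) && (hit_s < 0 || hit_s > pr$height)) next
            best <- tq
            break
          }
        }
      }
      if (is.finite(best) && best <= max_range) {
        rng <- best + if (noise_sigma > 0) stats::rnorm(1, 0, noise_sigma) else 0
        p_local <- rng * d_local          # sensor frame at acquisition time
        out_x <- c(out_x, p_local[1]); out_y <- c(out_y, p_local[2])
        out_z <- c(out_z, p_local[3])
        out_ring <- c(out_ring, r - 1L); out_t <- c(out_t, tj)
      }
    }
  }
  if (!length(out_x)) {
    warning("scan frame is empty: no ray intersections")
    cl <- point_cloud(numeric(0), numeric(0), numeric(0))
    return(list(cloud = cl, image = NULL))
  }
  cl <- point_cloud(out_x, out_y, out_z, ring = out_ring, t = out_t,
                    frame_id = "synthetic-frame")
  list(cloud = cl, image = project_to_range_image(cl, rows, cols))
}
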