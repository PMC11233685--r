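#' Height-measurement parameters
#'
#' @param W Axis-distance threshold, meters (default 0.15): points farther
#'   than `W` from the fitted stem axis are discarded before slicing.
#' @param d Window (slice) thickness, meters (default 0.02).
#' @param dw Width-jump margin, meters (default 0.10): a window is "wide"
#'   when its extent sum `a + b` exceeds `4R + dw`.
#' @param z_start Slicing start height, meters (default 0.5; below that,
#'   weeds and ground clutter corrupt the window extents).
#' @param run_length Number of consecutive wide windows that must be
#'   *exceeded* before a boundary is declared (default 10: a run of 11
#'   windows triggers). Short protrusion-induced spikes are thereby ignored.
#' @param min_boundary Plausibility floor for the boundary, meters (default
#'   1.2). A plant only enters the pipeline because its stem spans the
#'   1.0-1.2 m candidate slab, so a detected stem-leaf boundary below the
#'   slab top contradicts the segmentation evidence; such detections are
#'   flagged unmeasurable rather than reported. Set 0 to disable.
#' @return A `height_params` list.
#' @export
height_params <- function(W = 0.15, d = 0.02, dw = 0.10, z_start = 0.5,
                          run_length = 10L, min_boundary = 1.2) {
  stopifnot(W > 0, d > 0, dw > 0, z_start > 0, run_length >= 1)
  structure(list(W = W, d = d, dw = dw, z_start = z_start,
                 run_length = as.integer(run_length),
                 min_boundary = min_boundary),
            class = "height_params")
}

#' Keep points near the fitted stem axis
#'
#' Threshold segmentation: each point's perpendicular distance to the
#' cylinder axis line is computed and points with distance < `W` are
#' retained, stripping most leaf matter before window slicing.
#'
#' @param cloud One plant's [point_cloud()].
#' @param cylinder A `cylinder_fit` from [fit_cylinder_ransac()].
#' @param W Distance threshold, meters.
#' @return The filtered [point_cloud()].
#' @export
filter_near_axis <- function(cloud, cylinder, W = 0.15) {
  if (is.null(cylinder) || !isTRUE(cylinder$ok))
    stop("no cylinder fit for this plant; run measure_diameter first")
  m <- xyz(cloud)
  a <- cylinder$axis_point
  v <- cylinder$axis_dir / sqrt(sum(cylinder$axis_dir^2))
  d <- sweep(m, 2, a)
  proj <- d %*% v
  dist <- sqrt(pmax(0, rowSums(d^2) - proj^2))
  pc_subset(cloud, which(dist < W))
}

#' Slice a cloud into horizontal windows and compute extents
#'
#' Half-open windows `[z_start + i d, z_start + (i+1) d)` from bottom to top;
#' per window the extents `a = x_max - x_min` and `b = y_max - y_min` are
#' computed (0 for empty windows).
#'
#' @param cloud A normalized [point_cloud()] (typically axis-filtered).
#' @param params A [height_params()].
#' @return data.frame of window stats: `window_index` (0-based), `z_lo`,
#'   `z_hi`, `a`, `b`, `n_points`.
#' @export
slice_windows <- function(cloud, params = height_params()) {
  zmax <- if (nrow(cloud)) max(cloud$z) else -Inf
  if (zmax < params$z_start) {
    warning("cloud lies entirely below z_start; no windows")
    return(data.frame(window_index = integer(0), z_lo = numeric(0),
                      z_hi = numeric(0), a = numeric(0), b = numeric(0),
                      n_points = integer(0)))
  }
  # half-open windows; the 1e-9 snap sends an exact-edge point to the next
  # window, per the stated convention
  wi <- floor((cloud$z - params$z_start) / params$d + 1e-9)
  sel <- wi >= 0
  n_win <- max(wi[sel]) + 1L
  dt <- data.table::data.table(w = as.integer(wi[sel]),
                               x = cloud$x[sel], y = cloud$y[sel])
  agg <- dt[, list(a = max(x) - min(x), b = max(y) - min(y),
                   n_points = .N), by = "w"]
  out <- data.frame(window_index = 0:(n_win - 1L))
  out$z_lo <- params$z_start + out$window_index * params$d
  out$z_hi <- out$z_lo + params$d
  out$a <- 0; out$b <- 0; out$n_points <- 0L
  if (nrow(agg)) {
    j <- agg$w + 1L
    out$a[j] <- agg$a; out$b[j] <- agg$b; out$n_points[j] <- agg$n_points
  }
  out
}

#' Continuity-based stem-leaf boundary detection
#'
#' Scans the windows bottom-up. A window is "wide" iff `a + b > 4R + dw`.
#' Wide windows accumulate a run counter; a non-wide window resets it. When
#' the run exceeds `run_length`, the *first* window of the run is declared
#' the stem-leaf boundary — so a short wide spike (a leaf brushing the stem,
#' a surface protrusion) never triggers, which is exactly what a plain
#' single-window detector gets wrong.
#'
#' @param windows Window table from [slice_windows()].
#' @param R Pseudo-stem radius of the same plant (from the cylinder fit),
#'   meters.
#' @param params A [height_params()].
#' @return List with `found`, `boundary_window`, `boundary_z`
#'   (`= z_start + d * run_start_window`), `run_start_window`.
#' @export
detect_boundary <- function(windows, R, params = height_params()) {
  stopifnot(R > 0)
  thr <- 4 * R + params$dw
  run <- 0L; run_start <- NA_integer_
  for (i in seq_len(nrow(windows))) {
    wide <- (windows$a[i] + windows$b[i]) > thr
    if (wide) {
      if (run == 0L) run_start <- windows$window_index[i]
      run <- run + 1L
      if (run > params$run_length) {
        return(list(found = TRUE,
                    boundary_window = run_start,
                    boundary_z = params$z_start + params$d * run_start,
                    run_start_window = run_start))
      }
    } else {
      run <- 0L; run_start <- NA_integer_
    }
  }
  list(found = FALSE, boundary_window = NA_integer_, boundary_z = NA_real_,
       run_start_window = NA_integer_)
}

#' Measure one plant's pseudo-stem height
#'
#' Threshold segmentation around the fitted axis, bottom-up window slicing
#' and continuity boundary detection; the height is the z difference between
#' the boundary and the plant's base. After elevation normalization every
#' plant shares the ground datum z = 0, so the default base is
#' `min(z_min, 0)`: the datum unless the plant genuinely extends below it.
#' (`base = "zmin"` uses the literal lowest retained point, which inherits a
#' bias when ground removal truncates the stem foot.)
#'
#' @param cloud One plant's normalized [point_cloud()].
#' @param cylinder The plant's `cylinder_fit`.
#' @param params A [height_params()].
#' @param base `"datum"` (default) or `"zmin"`.
#' @return List with `height` (meters, NA when no boundary is found),
#'   `detection`, `windows`, `base_z`, `measurable`.
#' @export
measure_height <- function(cloud, cylinder, params = height_params(),
                           base = c("datum", "zmin")) {
  base <- match.arg(base)
  near <- filter_near_axis(cloud, cylinder, params$W)
  if (nrow(near) == 0)
    return(list(height = NA_real_, detection = NULL, windows = NULL,
                base_z = NA_real_, measurable = FALSE))
  windows <- slice_windows(near, params)
  det <- detect_boundary(windows, cylinder$radius, params)
  z_min <- min(near$z)
  base_z <- if (base == "datum") min(z_min, 0) else z_min
  if (!det$found)
    return(list(height = NA_real_, detection = det, windows = windows,
                base_z = base_z, measurable = FALSE))
  if (det$boundary_z < (params$min_boundary %||% 0))
    return(list(height = NA_real_, detection = det, windows = windows,
                base_z = base_z, measurable = FALSE))
  list(height = det$boundary_z - base_z, detection = det, windows = windows,
       base_z = base_z, measurable = TRUE)
}
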