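#' Project a point cloud to an organized range image
#'
#' Organizes one scan frame into a `rows x cols` grid (default 16 x 1800, the
#' resolution of a 16-beam scanner with 0.2 degree azimuth steps). Each point
#' maps to cell `(ring, floor(cols * azimuth / 2*pi))`; when two points
#' collide in a cell the nearer range wins. Column 0 sits at azimuth 0
#' (`atan2(y, x) = 0`), increasing counter-clockwise. Empty cells carry the
#' sentinel value -1 in both grids.
#'
#' @param cloud A [point_cloud()]. If it lacks a `ring` column, rings are
#'   derived from the elevation angle assuming 16 rows evenly spaced over
#'   \[-15, +15\] degrees (row 0 = lowest beam).
#' @param rows,cols Grid dimensions.
#' @return A `range_image`: list with `rows`, `cols`, `range` (meters, -1 for
#'   empty) and `index` (1-based source point index, -1 for empty).
#' @export
project_to_range_image <- function(cloud, rows = 16L, cols = 1800L) {
  m <- xyz(cloud)
  rng <- sqrt(rowSums(m^2))
  zero <- rng < 1e-12
  if (any(zero)) {
    warning(sprintf("skipping %d point(s) with zero norm", sum(zero)))
  }
  if ("ring" %in% names(cloud)) {
    ring <- cloud$ring
  } else {
    elev <- asin(pmin(1, pmax(-1, m[, 3] / pmax(rng, 1e-12)))) * 180 / pi
    step <- 30 / (rows - 1)
    ring <- as.integer(round((elev + 15) / step))
  }
  az <- atan2(m[, 2], m[, 1])
  az <- ifelse(az < 0, az + 2 * pi, az)
  col <- as.integer(floor(cols * az / (2 * pi))) %% cols
  ok <- !zero & ring >= 0L & ring < rows
  range_grid <- matrix(-1, rows, cols)
  index_grid <- matrix(-1L, rows, cols)
  idx <- which(ok)
  if (length(idx)) {
    # nearer-wins: process in decreasing range so the nearest overwrites last
    ordr <- idx[order(rng[idx], decreasing = TRUE)]
    cell <- cbind(ring[ordr] + 1L, col[ordr] + 1L)
    range_grid[cell] <- rng[ordr]
    index_grid[cell] <- ordr
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 range = range_grid, index = index_grid),
            class = "range_image")
}

#' @export
print.range_image <- function(x, ...) {
  filled <- sum(x$index > 0)
  cat(sprintf("range_image: %d x %d, %d cells filled (%.1f%%)\n",
              x$rows, x$cols, filled, 100 * filled / (x$rows * x$cols)))
  invisible(x)
}
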