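#' Construct a point cloud
#'
#' The universal currency of the pipeline: an unordered collection of 3D
#' points in meters, in a right-handed z-up frame, with optional per-point
#' scan-ring index, in-frame timestamp and intensity.
#'
#' @param x,y,z Numeric coordinate vectors (meters). Alternatively `x` may be
#'   an n x 3 matrix (or data.frame with columns x, y, z) and `y`, `z` omitted.
#' @param ring Optional integer scan-row index, 0-based, within `[0, 15]` for
#'   a 16-beam scanner.
#' @param t Optional per-point time in seconds within the frame.
#' @param intensity Optional unitless return intensity.
#' @param frame_id Free-text frame identifier.
#' @param is_normalized Logical; `TRUE` once ground elevation has been
#'   subtracted so the lowest ground level sits at z = 0.
#' @return An object of class `point_cloud`: a data.frame with columns
#'   `x`, `y`, `z` and any of `ring`, `t`, `intensity`, plus attributes
#'   `frame_id` and `is_normalized`.
#' @examples
#' pc <- point_cloud(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
#' n_points(pc)
#' @export
point_cloud <- function(x, y = NULL, z = NULL, ring = NULL, t = NULL,
                        intensity = NULL, frame_id = "", is_normalized = FALSE) {
  if (is.matrix(x) || is.data.frame(x)) {
    m <- x
    if (is.data.frame(m)) {
      stopifnot(all(c("x", "y", "z") %in% names(m)))
      if (is.null(ring) && !is.null(m$ring)) ring <- m$ring
      if (is.null(t) && !is.null(m$t)) t <- m$t
      if (is.null(intensity) && !is.null(m$intensity)) intensity <- m$intensity
      x <- m$x; y <- m$y; z <- m$z
    } else {
      stopifnot(ncol(m) >= 3)
      x <- m[, 1]; y <- m[, 2]; z <- m[, 3]
    }
  }
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  stopifnot(length(x) == length(y), length(y) == length(z))
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z)
  if (any(bad)) {
    warning(sprintf("dropping %d point(s) with non-finite coordinates", sum(bad)))
    keep <- !bad
    x <- x[keep]; y <- y[keep]; z <- z[keep]
    if (!is.null(ring)) ring <- ring[keep]
    if (!is.null(t)) t <- t[keep]
    if (!is.null(intensity)) intensity <- intensity[keep]
  }
  df <- data.frame(x = x, y = y, z = z)
  if (!is.null(ring)) {
    ring <- as.integer(ring)
    if (length(ring) && any(ring < 0L | ring > 63L, na.rm = TRUE))
      stop("ring index outside plausible sensor row range")
    df$ring <- ring
  }
  if (!is.null(t)) df$t <- as.numeric(t)
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  structure(df,
            frame_id = frame_id,
            is_normalized = isTRUE(is_normalized),
            class = c("point_cloud", "data.frame"))
}

#' Coerce to a point cloud
#' @param x Object to coerce (matrix or data.frame with x, y, z).
#' @param ... Passed to [point_cloud()].
#' @return A `point_cloud`.
#' @export
as_point_cloud <- function(x, ...) {
  if (inherits(x, "point_cloud")) return(x)
  point_cloud(x, ...)
}

#' Number of points in a cloud
#' @param cloud A `point_cloud`.
#' @return Integer count.
#' @export
n_points <- function(cloud) nrow(cloud)

#' Extract the coordinate matrix of a cloud
#' @param cloud A `point_cloud`.
#' @return An n x 3 numeric matrix with columns x, y, z.
#' @export
xyz <- function(cloud) {
  cbind(x = cloud$x, y = cloud$y, z = cloud$z)
}

#' Is the cloud elevation-normalized?
#' @param cloud A `point_cloud`.
#' @return Logical.
#' @export
is_normalized <- function(cloud) isTRUE(attr(cloud, "is_normalized"))

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points%s%s\n", nrow(x),
              if (nzchar(attr(x, "frame_id") %||% "")) paste0(" [", attr(x, "frame_id"), "]") else "",
              if (is_normalized(x)) " (elevation-normalized)" else ""))
  if (nrow(x) > 0) {
    r <- apply(xyz(x), 2, range)
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f] m\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  extras <- intersect(c("ring", "t", "intensity"), names(x))
  if (length(extras)) cat("  extra fields:", paste(extras, collapse = ", "), "\n")
  invisible(x)
}

# subset rows, keeping class and attributes
pc_subset <- function(cloud, idx) {
  out <- as.data.frame(cloud)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            frame_id = attr(cloud, "frame_id"),
            is_normalized = attr(cloud, "is_normalized"),
            class = c("point_cloud", "data.frame"))
}

# concatenate clouds; optional fields kept only if present in all parts
pc_bind <- function(...) {
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0, list(...))
  if (!length(parts)) return(point_cloud(numeric(), numeric(), numeric()))
  common <- Reduce(intersect, lapply(parts, names))
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)[, common, drop = FALSE]))
  rownames(out) <- NULL
  structure(out,
            frame_id = attr(parts[[1]], "frame_id"),
            is_normalized = attr(parts[[1]], "is_normalized"),
            class = c("point_cloud", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
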