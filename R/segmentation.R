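#' Segmentation parameters
#'
#' @param slab Height slab `c(z_lo, z_hi)` in meters above the normalized
#'   ground used to find pseudo-stems (default `c(1.0, 1.2)`, the band where
#'   stems are clear of weeds and most leaves).
#' @param Te Euclidean clustering distance threshold, meters (default 0.15:
#'   large enough to span the standoff between a stem surface and its peeling
#'   sheaths, far below the >= 2.5 m plant spacing).
#' @param T_width Footprint width threshold `T`, meters (default 0.6): slab
#'   clusters with `K = x_extent + y_extent > T` are pseudo-stem candidates.
#' @param min_cluster_size Minimum surviving cluster size, points.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(slab = c(1.0, 1.2), Te = 0.15, T_width = 0.6,
                                min_cluster_size = 30L) {
  stopifnot(slab[1] < slab[2], Te > 0, T_width > 0)
  structure(list(slab = slab, Te = Te, T_width = T_width,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "segmentation_params")
}

#' Extract the height slab of a normalized cloud
#'
#' Returns points with `z_lo <= z <= z_hi` (closed interval).
#'
#' @param cloud A normalized [point_cloud()].
#' @param slab `c(z_lo, z_hi)`, meters.
#' @return The slab [point_cloud()]; row indices into the input attached as
#'   attribute `source_indices`.
#' @export
extract_height_slab <- function(cloud, slab = c(1.0, 1.2)) {
  keep <- which(cloud$z >= slab[1] & cloud$z <= slab[2])
  if (!length(keep)) warning("height slab is empty")
  out <- pc_subset(cloud, keep)
  attr(out, "source_indices") <- keep
  out
}

#' Euclidean clustering
#'
#' Connected components of the graph linking points within distance `Te`;
#' clusters smaller than `min_cluster_size` are discarded.
#'
#' @param cloud A [point_cloud()] (or n x 3 matrix).
#' @param Te Linking distance, meters.
#' @param min_cluster_size Minimum cluster size in points.
#' @return Integer vector of per-point cluster ids (0 = discarded), with
#'   cluster ids renumbered 1..k by decreasing size.
#' @export
euclidean_cluster <- function(cloud, Te, min_cluster_size = 1L) {
  m <- if (is.matrix(cloud)) cloud else xyz(cloud)
  if (nrow(m) == 0) return(integer(0))
  lab <- .euclidean_cluster_cpp(m, Te)
  tab <- tabulate(lab)
  keep_ids <- which(tab >= min_cluster_size)
  keep_ids <- keep_ids[order(tab[keep_ids], decreasing = TRUE)]
  remap <- integer(length(tab))
  remap[keep_ids] <- seq_along(keep_ids)
  out <- ifelse(lab > 0, remap[lab], 0L)
  as.integer(out)
}

#' Select pseudo-stem candidates from slab clusters
#'
#' For each cluster the footprint width `K = (x_max - x_min) + (y_max -
#' y_min)` is computed; clusters with `K > T` are kept as pseudo-stem
#' candidates, re-filtered with SOR, and summarized by their centroid.
#'
#' @param slab_cloud The slab [point_cloud()].
#' @param labels Cluster labels from [euclidean_cluster()].
#' @param T_width Width threshold `T`, meters.
#' @param refilter Apply SOR to each kept cluster before computing the
#'   centroid (default TRUE).
#' @return A data.frame of candidates: `cluster_id`, `K`, `centroid_x/y/z`,
#'   `n_points`; the member indices are attached as attribute `members`
#'   (list of integer vectors into `slab_cloud`).
#' @export
select_stem_candidates <- function(slab_cloud, labels, T_width = 0.6,
                                   refilter = TRUE) {
  ids <- setdiff(sort(unique(labels)), 0L)
  rows <- list(); members <- list()
  for (id in ids) {
    idx <- which(labels == id)
    cl <- pc_subset(slab_cloud, idx)
    K <- (max(cl$x) - min(cl$x)) + (max(cl$y) - min(cl$y))
    if (K > T_width) {
      if (refilter && nrow(cl) > 20) {
        f <- statistical_outlier_removal(cl)
        rm <- attr(f, "removed")
        if (length(rm)) { cl <- f; idx <- idx[-rm] }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = id, K = K,
        centroid_x = mean(cl$x), centroid_y = mean(cl$y), centroid_z = mean(cl$z),
        n_points = nrow(cl))
      members[[length(members) + 1L]] <- idx
    }
  }
  if (!length(rows)) {
    warning("no slab cluster passed the width threshold; no stem candidates")
    out <- data.frame(cluster_id = integer(0), K = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      centroid_z = numeric(0), n_points = integer(0))
    attr(out, "members") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Assign every point to a plant by centroid-seeded K-means
#'
#' Lloyd K-means in XY only (plant membership is horizontal proximity to a
#' stem; using z would drag canopy points toward tall neighbours), with
#' k = number of candidates and centers initialized at the candidate
#' centroids.
#'
#' @param cloud The full ground-removed [point_cloud()].
#' @param candidates Candidate table from [select_stem_candidates()].
#' @param max_iters Lloyd iteration cap (default 100).
#' @return A `plant_segmentation`: list with `labels` (per-point plant id,
#'   1..k), `candidates`, `n_plants`, `centers` (final XY centers).
#' @export
kmeans_assign_plants <- function(cloud, candidates, max_iters = 100L) {
  if (nrow(candidates) < 1) stop("kmeans_assign_plants requires at least one candidate")
  if (nrow(cloud) == 0) stop("cannot assign plants in an empty cloud")
  xy <- cbind(cloud$x, cloud$y)
  centers <- as.matrix(candidates[, c("centroid_x", "centroid_y")])
  if (nrow(candidates) == 1L) {
    labels <- rep(1L, nrow(cloud))
    centers_out <- matrix(colMeans(xy), 1, 2)
  } else {
    km <- suppressWarnings(
      stats::kmeans(xy, centers = centers, iter.max = max_iters,
                    algorithm = "Lloyd"))
    labels <- km$cluster
    centers_out <- km$centers
  }
  structure(list(labels = as.integer(labels), candidates = candidates,
                 n_plants = nrow(candidates), centers = centers_out),
            class = "plant_segmentation")
}

#' Segment individual plants
#'
#' The full single-plant isolation pass: extract the 1.0-1.2 m slab, SOR it,
#' Euclidean-cluster it, keep clusters whose footprint width exceeds `T` as
#' pseudo-stem candidates, then partition the whole cloud among the
#' candidates with centroid-seeded K-means.
#'
#' @param cloud A normalized, ground-removed [point_cloud()].
#' @param params A [segmentation_params()].
#' @return A `plant_segmentation` (see [kmeans_assign_plants()]); `labels`
#'   has one entry per point of `cloud`.
#' @export
segment_plants <- function(cloud, params = segmentation_params()) {
  slab <- extract_height_slab(cloud, params$slab)
  if (nrow(slab) == 0) stop("no points in the height slab; is the cloud normalized?")
  if (nrow(slab) > 20) {
    f <- statistical_outlier_removal(slab)
    rm <- attr(f, "removed")
    if (length(rm)) {
      src <- attr(slab, "source_indices")[-rm]
      slab <- f
      attr(slab, "source_indices") <- src
    }
  }
  labels <- euclidean_cluster(slab, params$Te, params$min_cluster_size)
  candidates <- select_stem_candidates(slab, labels, params$T_width)
  if (nrow(candidates) == 0)
    stop("no pseudo-stem candidates found (width threshold T may be too high)")
  kmeans_assign_plants(cloud, candidates)
}

#' Extract one plant's cloud from a segmentation
#'
#' @param cloud The cloud passed to [segment_plants()].
#' @param seg A `plant_segmentation`.
#' @param plant_id Plant id in `1..seg$n_plants`.
#' @return The plant's [point_cloud()].
#' @export
plant_cloud <- function(cloud, seg, plant_id) {
  pc_subset(cloud, which(seg$labels == plant_id))
}

#' @export
print.plant_segmentation <- function(x, ...) {
  cat(sprintf("plant_segmentation: %d plants, %d labelled points\n",
              x$n_plants, length(x$labels)))
  invisible(x)
}
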