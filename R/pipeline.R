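#' Run the full phenotyping pipeline
#'
#' Orchestrates simulate/load -> preprocess -> segment -> diameter -> height
#' -> evaluate, producing a per-plant phenotype table and (when truth is
#' available) accuracy summaries. Fully deterministic given the seeds in the
#' configuration.
#'
#' @param config A configuration list, or a path to a YAML/JSON file holding
#'   one. Recognized blocks (all optional except one of `simulate` /
#'   `input`):
#'   \describe{
#'     \item{simulate}{Arguments for [orchard_config()].}
#'     \item{input}{`list(path =, format =)` for [read_point_cloud()].}
#'     \item{truth}{Path to a truth CSV (plant_id, base_x, base_y,
#'       diameter_m, height_m) when loading external data.}
#'     \item{preprocess}{`crop`, `sor_k`, `sor_mult`, `cell_size`,
#'       `plane_threshold`.}
#'     \item{segment}{Arguments for [segmentation_params()].}
#'     \item{diameter}{`method`, `band`, `inlier_threshold`, `max_iters`.}
#'     \item{height}{Arguments for [height_params()] plus `base`.}
#'     \item{seed}{Master seed (default 1).}
#'     \item{output_dir}{If set, writes `phenotypes.csv` and `summary.json`.}
#'   }
#' @return A `phenotype_report`: list with `phenotypes` (per-plant rows),
#'   `summary` (per-trait metric rows or NULL), `matched` (candidate-truth
#'   matching), `config`, `seed`, `n_plants_detected`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  seed <- as.integer(cfg$seed %||% 1L)
  truths <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    orch_cfg <- do.call(orchard_config, sim_args)
    orch <- generate_orchard(orch_cfg)
    cloud <- orch$cloud
    truths <- orch$truths
  } else if (!is.null(cfg$input)) {
    cloud <- read_point_cloud(cfg$input$path, cfg$input$format %||% "auto")
    if (!is.null(cfg$truth)) {
      truths <- utils::read.csv(cfg$truth)
    }
  } else {
    stop("config must contain a 'simulate' or an 'input' block")
  }

  pp_args <- cfg$preprocess %||% list()
  pre <- preprocess_cloud(cloud,
                          crop = pp_args$crop,
                          sor_k = pp_args$sor_k %||% 16L,
                          sor_mult = pp_args$sor_mult %||% 1.0,
                          cell_size = pp_args$cell_size %||% 0.5,
                          rigidity = pp_args$rigidity %||% 3L,
                          plane_threshold = pp_args$plane_threshold %||% 0.05,
                          seed = seed)
  veg <- pre$cloud

  seg_args <- cfg$segment %||% list()
  sp <- do.call(segmentation_params, seg_args)
  seg <- segment_plants(veg, sp)

  di_args <- cfg$diameter %||% list()
  hp_args <- cfg$height %||% list()
  height_base <- hp_args$base %||% "datum"
  hp_args$base <- NULL
  hp <- do.call(height_params, hp_args)

  n <- seg$n_plants
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pc <- plant_cloud(veg, seg, i)
    md <- measure_diameter(pc,
                           method = di_args$method %||% "ransac",
                           band = di_args$band %||% c(1.0, 1.2),
                           inlier_threshold = di_args$inlier_threshold %||% 0.04,
                           max_iters = di_args$max_iters %||% 2000L,
                           seed = seed + i)
    h <- NA_real_; h_flag <- "no_cylinder"
    if (md$measurable && inherits(md$fit, "cylinder_fit")) {
      mh <- measure_height(pc, md$fit, hp, base = height_base)
      h <- mh$height
      h_flag <- if (mh$measurable) "ok" else "no_boundary"
    }
    rows[[i]] <- data.frame(
      plant_id = i,
      center_x = seg$candidates$centroid_x[i],
      center_y = seg$candidates$centroid_y[i],
      diameter_m = md$diameter,
      height_m = h,
      diameter_flag = if (md$measurable) "ok" else "unmeasurable",
      height_flag = h_flag)
  }
  phen <- do.call(rbind, rows)

  summary_df <- NULL; matched <- NULL
  if (!is.null(truths)) {
    matched <- match_plants(phen, truths)
    dm <- phen$diameter_m[matched$detected_id]
    hm <- phen$height_m[matched$detected_id]
    summary_df <- rbind(
      cbind(trait = "diameter", metric_summary(dm, truths$diameter_m[matched$truth_id])),
      cbind(trait = "height", metric_summary(hm, truths$height_m[matched$truth_id])))
  }

  report <- structure(list(phenotypes = phen, summary = summary_df,
                           matched = matched, config = cfg, seed = seed,
                           n_plants_detected = n),
                      class = "phenotype_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' Match detected plants to ground-truth records
#'
#' Greedy 1:1 matching of detected plant centers to true stem bases by XY
#' distance (closest pairs first), within `max_dist`.
#'
#' @param phen Phenotype rows with `center_x`, `center_y`.
#' @param truths Truth table with `base_x`, `base_y`.
#' @param max_dist Matching radius, meters.
#' @return data.frame with `truth_id`, `detected_id`, `dist`.
#' @export
match_plants <- function(phen, truths, max_dist = 0.75) {
  if (!nrow(phen) || !nrow(truths))
    return(data.frame(truth_id = integer(0), detected_id = integer(0),
                      dist = numeric(0)))
  D <- outer(truths$base_x, phen$center_x, `-`)^2 +
    outer(truths$base_y, phen$center_y, `-`)^2
  D <- sqrt(D)
  pairs <- which(D <= max_dist, arr.ind = TRUE)
  if (!nrow(pairs))
    return(data.frame(truth_id = integer(0), detected_id = integer(0),
                      dist = numeric(0)))
  ord <- order(D[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_t <- logical(nrow(truths)); used_d <- logical(nrow(phen))
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    ti <- pairs[k, 1]; di <- pairs[k, 2]
    if (used_t[ti] || used_d[di]) next
    used_t[ti] <- TRUE; used_d[di] <- TRUE
    out[[length(out) + 1L]] <- data.frame(truth_id = ti, detected_id = di,
                                          dist = D[ti, di])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Segmentation success rate against truth
#'
#' Fraction of true plants matched 1:1 to a detected plant (unique matches /
#' number of plants) — the per-stand accuracy used when tuning the width
#' threshold `T`.
#'
#' @param seg A `plant_segmentation`.
#' @param truths Truth table with `base_x`, `base_y`.
#' @param max_dist Matching radius, meters.
#' @return Success rate in `[0, 1]`.
#' @export
segmentation_success_rate <- function(seg, truths, max_dist = 0.75) {
  phen <- data.frame(center_x = seg$candidates$centroid_x,
                     center_y = seg$candidates$centroid_y)
  m <- match_plants(phen, truths, max_dist)
  # a truth matched by exactly one candidate counts; extra candidates don't
  nrow(m) / nrow(truths)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      config <- yaml::read_yaml(config)
    } else if (ext == "json") {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else stop("unrecognized config file type: ", config)
  }
  stopifnot(is.list(config))
  config
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  summary_list <- if (is.null(report$summary)) list(available = FALSE)
                  else c(list(available = TRUE), as.list(split(report$summary, report$summary$trait)))
  jsonlite::write_json(list(seed = report$seed,
                            n_plants_detected = report$n_plants_detected,
                            summary = summary_list),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(sprintf("phenotype_report: %d plants detected (seed %d)\n",
              x$n_plants_detected, x$seed))
  ok_d <- sum(x$phenotypes$diameter_flag == "ok")
  ok_h <- sum(x$phenotypes$height_flag == "ok")
  cat(sprintf("  diameter measured for %d, height for %d\n", ok_d, ok_h))
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      s <- x$summary[i, ]
      cat(sprintf("  %s: n=%d RMSE=%.4f m MAE=%.4f m MAPE=%.2f%% R2=%.4f\n",
                  s$trait, s$n, s$rmse, s$mae, s$mape, s$r_squared))
    }
  }
  invisible(x)
}
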