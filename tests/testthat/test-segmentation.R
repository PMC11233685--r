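test_that("height-slab extraction uses a closed interval on normalized z", {
  pc <- point_cloud(rep(0, 5), rep(0, 5), c(0.5, 1.0, 1.1, 1.2, 1.3))
  attr(pc, "is_normalized") <- TRUE
  slab <- extract_height_slab(pc, c(1.0, 1.2))
  expect_equal(sort(slab$z), c(1.0, 1.1, 1.2))   # boundaries included
  # a 0.9 m plant contributes nothing; warning on empty slab
  short <- point_cloud(0, 0, 0.9)
  expect_warning(s2 <- extract_height_slab(short), "empty")
  expect_equal(n_points(s2), 0)
})

test_that("Euclidean clustering separates and merges blobs by the linking distance", {
  set.seed(41)
  ball <- function(n, c0) {
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2)) * runif(n)^(1/3)   # dense unit-radius blob
    sweep(u, 2, c0, `+`)
  }
  m <- rbind(ball(4000, c(0, 0, 0)), ball(4000, c(5, 5, 0)))
  lab_small <- euclidean_cluster(m, 0.2)
  expect_equal(length(setdiff(unique(lab_small), 0L)), 2)
  lab_big <- euclidean_cluster(m, 6)
  expect_equal(length(setdiff(unique(lab_big), 0L)), 1)
})

test_that("Euclidean clustering equals the quadratic union-find oracle", {
  set.seed(42)
  for (rep in 1:3) {
    n <- sample(200:500, 1)
    m <- cbind(runif(n, 0, 3), runif(n, 0, 3), runif(n, 0, 1))
    eps <- runif(1, 0.05, 0.3)
    got <- euclidean_cluster(m, eps, min_cluster_size = 1L)
    want <- brute_force_cluster(m, eps)
    expect_equal(canonical_partition(got), canonical_partition(want))
    # partition property: sizes sum to the surviving point count
    expect_equal(sum(tabulate(got)), n)
  }
})

test_that("candidate selection applies the footprint-width rule K > T", {
  # cluster with x-extent 0.4, y-extent 0.3 -> K = 0.7 (kept at T = 0.6)
  c1 <- point_cloud(runif(60, 0, 0.4), runif(60, 0, 0.3), runif(60, 1, 1.2))
  # cluster with extents 0.2 x 0.2 -> K = 0.4 (rejected)
  c2 <- point_cloud(3 + runif(60, 0, 0.2), 3 + runif(60, 0, 0.2), runif(60, 1, 1.2))
  slab <- stemscan:::pc_bind(c1, c2)
  # make extents exact
  slab$x[1] <- 0; slab$x[2] <- 0.4; slab$y[1] <- 0; slab$y[2] <- 0.3
  slab$x[61] <- 3; slab$x[62] <- 3.2; slab$y[61] <- 3; slab$y[62] <- 3.2
  labels <- rep(c(1L, 2L), each = 60)
  cand <- select_stem_candidates(slab, labels, T_width = 0.6, refilter = FALSE)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$K, 0.7, tolerance = 1e-9)
  expect_equal(cand$cluster_id, 1L)
  expect_warning(none <- select_stem_candidates(slab, labels, T_width = 2),
                 "no slab cluster")
  expect_equal(nrow(none), 0)
})

test_that("K-means assignment is seeded, exhaustive and order-invariant", {
  set.seed(43)
  p1 <- cylinder_points(400, center = c(1, 1), z0 = 0, height = 1.6, sigma = 0.01)
  p2 <- cylinder_points(400, center = c(6, 6), z0 = 0, height = 1.6, sigma = 0.01)
  cl <- point_cloud(rbind(p1, p2))
  cand <- data.frame(cluster_id = 1:2, K = c(0.7, 0.7),
                     centroid_x = c(1, 6), centroid_y = c(1, 6),
                     centroid_z = c(1.1, 1.1), n_points = c(50, 50))
  seg <- kmeans_assign_plants(cl, cand)
  expect_equal(seg$n_plants, 2)
  expect_equal(length(seg$labels), 800)
  expect_true(all(seg$labels[1:400] == seg$labels[1]))       # pure plants
  expect_true(all(seg$labels[401:800] == seg$labels[401]))
  expect_true(seg$labels[1] != seg$labels[401])
  # permuting candidates permutes labels but not the partition
  seg2 <- kmeans_assign_plants(cl, cand[2:1, ])
  expect_equal(canonical_partition(seg$labels), canonical_partition(seg2$labels))
  # one candidate: everything in one plant
  seg1 <- kmeans_assign_plants(cl, cand[1, ])
  expect_true(all(seg1$labels == 1L))
  expect_error(kmeans_assign_plants(cl, cand[0, ]), "at least one")
})

test_that("full segmentation isolates every plant of the small orchard", {
  orch <- generate_orchard(small_orchard_config(seed = 44))
  pre <- preprocess_cloud(orch$cloud, seed = 44)
  seg <- segment_plants(pre$cloud)
  expect_equal(seg$n_plants, nrow(seg$candidates))
  expect_equal(length(seg$labels), n_points(pre$cloud))
  expect_equal(segmentation_success_rate(seg, orch$truths), 1.0)
  # stems purely assigned: each true plant's stem points carry one label
  lab <- orch$labels[pre$kept, ]
  for (i in seq_len(nrow(orch$truths))) {
    li <- seg$labels[lab$component == "stem" & lab$plant_id == i]
    expect_gt(mean(li == as.integer(names(which.max(table(li))))), 0.99)
  }
})

test_that("an over-tight width threshold degrades segmentation (trend check)", {
  orch <- generate_orchard(orchard_config(n_plants = 8, seed = 45,
                                          min_spacing = 1.6, plot_size = 9))
  pre <- preprocess_cloud(orch$cloud, seed = 45)
  s06 <- segment_plants(pre$cloud, segmentation_params(T_width = 0.6))
  r06 <- segmentation_success_rate(s06, orch$truths)
  r10 <- tryCatch({
    s10 <- segment_plants(pre$cloud, segmentation_params(T_width = 1.0))
    segmentation_success_rate(s10, orch$truths)
  }, error = function(e) 0)
  expect_lt(r10, r06)
  expect_gte(r06, 0.85)
})

test_that("success rate does not improve as plants crowd together", {
  rates <- sapply(c(2.5, 1.0), function(sp) {
    orch <- generate_orchard(orchard_config(n_plants = 6, plot_size = 10,
                                            min_spacing = sp, seed = 46))
    pre <- preprocess_cloud(orch$cloud, seed = 46)
    tryCatch(segmentation_success_rate(segment_plants(pre$cloud), orch$truths),
             error = function(e) 0)
  })
  expect_lte(rates[2], rates[1])
})
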