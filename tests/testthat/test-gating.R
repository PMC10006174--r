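test_that("mean-shift finds two separated blobs and matches ground truth", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
               matrix(rnorm(100, 8, 0.3), 50, 2))
  truth <- rep(1:2, each = 50)
  cl <- cluster_embedding(pts, bandwidth = 1)
  expect_equal(cl$n_clusters, 2)
  expect_equal(length(unique(paste(cl$labels, truth))), 2)
})

test_that("mean-shift limits: single point, huge bandwidth, bad bandwidth", {
  cl1 <- cluster_embedding(matrix(c(1, 2), 1, 2))
  expect_equal(cl1$n_clusters, 1)
  set.seed(5)
  pts <- matrix(rnorm(60), 30, 2)
  cl2 <- cluster_embedding(pts, bandwidth = 1000)
  expect_equal(cl2$n_clusters, 1)
  expect_error(cluster_embedding(pts, bandwidth = -1), "positive")
})

test_that("clustering is invariant to point order", {
  set.seed(12)
  pts <- rbind(matrix(rnorm(60, 0, 0.4), 30, 2),
               matrix(rnorm(60, 6, 0.4), 30, 2),
               matrix(c(rnorm(30, 0, 0.4), rnorm(30, 6, 0.4)), 30, 2))
  cl <- cluster_embedding(pts, bandwidth = 1)
  perm <- sample(nrow(pts))
  cl_p <- cluster_embedding(pts[perm, ], bandwidth = 1)
  # identical partitions: co-membership matrices agree
  co <- outer(cl$labels, cl$labels, "==")
  co_p <- outer(cl_p$labels, cl_p$labels, "==")[order(perm), order(perm)]
  expect_identical(co, co_p)
})

test_that("weights steer mean-shift modes toward heavy points", {
  pts <- rbind(c(0, 0), c(0.4, 0), c(10, 0))
  cl <- cluster_embedding(pts, weights = c(100, 1, 50), bandwidth = 1)
  expect_equal(cl$n_clusters, 2)
  expect_equal(cl$labels[1], cl$labels[2])
})

test_that("scale-0 expansion is a passthrough of per-pixel labels", {
  fx <- two_blob_fixture(n = 12, seed = 3)
  g <- build_knn_graph(fx$table, k = 4)
  h <- build_hierarchy(g, n_scales = 1, seed = 1)
  labels <- fx$labels - 1L                  # 0-based cluster labels
  lab <- expand_to_pixels(h, 0, labels)
  got <- lab$label_map[cbind(fx$table$coords[, 1] + 1L,
                             fx$table$coords[, 2] + 1L)]
  expect_equal(got, fx$labels)
  # every pixel holds exactly one label or background
  expect_true(all(lab$label_map %in% c(0L, 1L, 2L)))
})

test_that("expansion through a landmark scale recovers blob membership", {
  fx <- two_blob_fixture(n = 150, seed = 13)
  g <- build_knn_graph(fx$table, k = 10)
  h <- build_hierarchy(g, n_scales = 2, seed = 3)
  land_labels <- fx$labels[h$scales[[2]]$landmark_indices] - 1L
  lab <- expand_to_pixels(h, 1, land_labels)
  got <- lab$label_map[cbind(fx$table$coords[, 1] + 1L,
                             fx$table$coords[, 2] + 1L)]
  expect_gte(mean(got == fx$labels), 0.95)
  expect_error(expand_to_pixels(h, 1, land_labels[-1]), "landmarks")
})

test_that("argmax expansion equals the explicit composed-matrix product", {
  fx <- two_blob_fixture(n = 40, seed = 9)
  g <- build_knn_graph(fx$table, k = 8)
  # 80 points may not sustain 3 scales; truncation is fine for this oracle
  h <- suppressWarnings(build_hierarchy(g, n_scales = 3, seed = 5))
  s_top <- n_scales(h) - 1L
  # oracle: dense product of the per-scale influence matrices
  dense <- diag(h$n_pixels)
  for (s in seq_len(s_top)) {
    dense <- dense %*% as.matrix(h$scales[[s + 1L]]$influence)
  }
  oracle <- apply(dense, 1, function(r) which(r == max(r))[1])
  expect_equal(hard_assignment(h, s_top), as.integer(oracle))
})

test_that("signature matching names clusters in gating-priority order", {
  # three planted clusters: T cell (CD3+CD7+), ILC (CD3-CD7+), none
  sig <- matrix(c(5, 5, 0,
                  0, 5, 0,
                  0, 0, 0),
                3, 3, byrow = TRUE,
                dimnames = list(NULL, c("CD3", "CD7", "CD20")))
  fx <- generate_pixel_clusters(40, sig, noise_model = "gaussian",
                                sigma = 0.2, seed = 8)
  g <- build_knn_graph(fx$table, k = 6)
  h <- build_hierarchy(g, n_scales = 1, seed = 1)
  lab <- expand_to_pixels(h, 0, fx$labels - 1L)
  sigs <- signature_table(c("T cell", "ILC"),
                          positive = list(c("CD3", "CD7"), "CD7"),
                          negative = list(character(0), "CD3"))
  named <- assign_cell_types(lab, fx$table, sigs,
                             positivity_quantile = 0.6)
  expect_equal(unname(named$class_names[as.character(1)]), "T cell")
  expect_equal(unname(named$class_names[as.character(2)]), "ILC")
  expect_equal(unname(named$class_names[as.character(3)]), "unassigned")
})

test_that("a cluster matching several signatures takes the first and warns", {
  sig <- matrix(c(5, 5), 1, 2, dimnames = list(NULL, c("CD3", "CD7")))
  fx <- generate_pixel_clusters(30, rbind(sig, c(0, 0)),
                                noise_model = "gaussian", sigma = 0.1,
                                seed = 4)
  g <- build_knn_graph(fx$table, k = 5)
  h <- build_hierarchy(g, n_scales = 1, seed = 1)
  lab <- expand_to_pixels(h, 0, fx$labels - 1L)
  sigs <- signature_table(c("first", "second"),
                          positive = list("CD3", c("CD3", "CD7")))
  expect_warning(named <- assign_cell_types(lab, fx$table, sigs),
                 "several signatures")
  expect_equal(unname(named$class_names["1"]), "first")
  expect_error(assign_cell_types(lab, fx$table,
                                 signature_table("x", list("nope"))),
               "absent")
})

test_that("clusters sharing a name merge into one rendered class", {
  lm <- matrix(0L, 4, 4)
  lm[1, 1] <- 1L; lm[2, 2] <- 2L; lm[3, 3] <- 3L; lm[4, 4] <- 4L
  labeling <- structure(
    list(label_map = lm,
         class_names = setNames(c("T cell", "T cell", "unassigned", "ILC"),
                                1:4)),
    class = "pixel_labeling")
  merged <- merge_labels_by_name(labeling)
  expect_equal(unname(merged$class_names),
               c("T cell", "unassigned", "ILC"))
  expect_equal(merged$label_map[1, 1], merged$label_map[2, 2])
  expect_equal(sum(merged$label_map > 0), 4)
  dropped <- merge_labels_by_name(labeling, drop_unassigned = TRUE)
  expect_false("unassigned" %in% dropped$class_names)
  expect_equal(dropped$label_map[3, 3], 0L)
  expect_equal(sum(dropped$label_map > 0), 3)
})

test_that("positivity thresholds expose positive and dim gates", {
  fx <- two_blob_fixture(n = 50, seed = 2)
  thr <- positivity_thresholds(fx$table)
  expect_length(thr$positive, 3)
  expect_true(all(thr$dim <= thr$positive))
})
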