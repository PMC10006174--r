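make_table <- function(values) {
  values <- as.matrix(values)
  pixel_table(values, cbind(0:(nrow(values) - 1L), 0L),
              paste0("m", seq_len(ncol(values))), c(nrow(values), 1L))
}

test_that("kNN neighbors match brute-force all-pairs distances", {
  tab <- make_table(c(0, 1, 10))
  g <- build_knn_graph(tab, k = 1)
  expect_equal(g$neighbors[, 1], c(2L, 1L, 2L))   # 0->1, 1->0, 10->1
  expect_equal(g$dist[, 1], c(1, 1, 9))
  # k = n-1 gives the complete digraph
  g2 <- build_knn_graph(tab, k = 2)
  expect_equal(sort(g2$neighbors[1, ]), c(2L, 3L))
  expect_equal(sort(g2$neighbors[3, ]), c(1L, 2L))
})

test_that("duplicated rows give zero-distance neighbors but no self-edges", {
  tab <- make_table(c(5, 5, 5, 9))
  g <- build_knn_graph(tab, k = 2)
  for (i in 1:4) expect_false(i %in% g$neighbors[i, ])
  expect_equal(g$dist[1, 1], 0)
  expect_true(all(g$weights >= 0))
})

test_that("oversized k is clamped with a warning", {
  tab <- make_table(c(1, 2, 3))
  expect_warning(g <- build_knn_graph(tab, k = 10), "clamp")
  expect_equal(g$k, 2)
})

test_that("exact and kd-tree neighbor searches agree", {
  set.seed(8)
  x <- matrix(rnorm(300 * 4), 300, 4)
  tab <- make_table(x)
  g_exact <- build_knn_graph(tab, k = 5)
  nn <- RANN::nn2(x, k = 6)
  expect_equal(g_exact$neighbors, nn$nn.idx[, -1], ignore_attr = TRUE)
})

test_that("a one-scale hierarchy is the identity over pixels", {
  fx <- two_blob_fixture(n = 15)
  g <- build_knn_graph(fx$table, k = 5)
  h <- build_hierarchy(g, n_scales = 1, seed = 1)
  expect_equal(n_scales(h), 1)
  expect_equal(hard_assignment(h, 0), 1:30)
  expect_equal(as.matrix(compose_influence(h, 0)),
               diag(30), ignore_attr = TRUE)
  # drill on a single "landmark" (pixel) returns exactly that pixel
  one <- drill_down(h, 0, 7)
  expect_equal(nrow(one$values), 1)
  expect_equal(one$values[1, ], fx$table$values[7, ], ignore_attr = TRUE)
})

test_that("landmarks cover both blobs and influence stays within blobs", {
  fx <- two_blob_fixture(n = 150, seed = 13)
  g <- build_knn_graph(fx$table, k = 10)
  h <- build_hierarchy(g, n_scales = 2, seed = 3)
  expect_equal(n_scales(h), 2)
  land_scale0 <- h$scales[[2]]$landmark_indices
  land_labels <- fx$labels[land_scale0]
  expect_setequal(unique(land_labels), c(1L, 2L))
  # cross-blob influence mass, summed by brute force over the dense matrix
  infl <- as.matrix(h$scales[[2]]$influence)
  cross <- 0
  for (i in seq_len(nrow(infl))) {
    cross <- cross + sum(infl[i, land_labels != fx$labels[i]])
  }
  expect_lt(cross / nrow(infl), 0.05)
})

test_that("influence rows are stochastic and weights conserve pixel count", {
  fx <- two_blob_fixture(n = 100, seed = 5)
  g <- build_knn_graph(fx$table, k = 10)
  h <- build_hierarchy(g, n_scales = 3, seed = 9)
  for (s in seq_len(n_scales(h) - 1L)) {
    infl <- h$scales[[s + 1L]]$influence
    expect_lt(max(abs(Matrix::rowSums(infl) - 1)), 1e-6)
    expect_lt(abs(sum(h$scales[[s + 1L]]$landmark_weight) - h$n_pixels),
              1e-3)
    expect_true(all(h$scales[[s + 1L]]$landmark_weight > 0))
  }
  # landmark counts strictly decrease; composed map is row-stochastic
  counts <- vapply(h$scales, `[[`, integer(1), "n_points")
  expect_true(all(diff(counts) < 0))
  comp <- compose_influence(h, n_scales(h) - 1L)
  expect_lt(max(abs(Matrix::rowSums(comp) - 1)), 1e-6)
})

test_that("hierarchies too deep for the data are truncated with a warning", {
  fx <- two_blob_fixture(n = 8, seed = 2)
  g <- build_knn_graph(fx$table, k = 3)
  expect_warning(h <- build_hierarchy(g, n_scales = 4, seed = 1),
                 "truncated")
  expect_lt(n_scales(h), 4)
})

test_that("embedding is deterministic and degenerate inputs are handled", {
  fx <- two_blob_fixture(n = 40, seed = 6)
  g <- build_knn_graph(fx$table, k = 8)
  h <- build_hierarchy(g, n_scales = 2, seed = 2)
  e1 <- embed_scale(h, 1, params = list(iterations = 120), seed = 11)
  e2 <- embed_scale(h, 1, params = list(iterations = 120), seed = 11)
  expect_identical(e1$points, e2$points)
  expect_true(all(is.finite(e1$points)))
  expect_error(embed_scale(h, 5), "scale 5")
})

test_that("separated classes stay separated in the data-scale embedding", {
  fx <- two_blob_fixture(n = 50, seed = 21)
  g <- build_knn_graph(fx$table, k = 10)
  h <- build_hierarchy(g, n_scales = 1, seed = 1)
  e <- embed_scale(h, 0, params = list(iterations = 400), seed = 3)
  # mean silhouette of the true labels in the 2-D layout
  d <- as.matrix(dist(e$points))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    same <- fx$labels == fx$labels[i]
    a <- mean(d[i, same & seq_along(same) != i])
    b <- mean(d[i, !same])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("drill-down selections capture their blob and partition pixels", {
  fx <- two_blob_fixture(n = 150, seed = 13)
  g <- build_knn_graph(fx$table, k = 10)
  h <- build_hierarchy(g, n_scales = 2, seed = 3)
  land_labels <- fx$labels[h$scales[[2]]$landmark_indices]
  sel_a <- which(land_labels == 1L)
  tab_a <- drill_down(h, 1, sel_a)
  # >= 95% of returned pixels truly belong to blob A
  got <- fx$labels[tab_a$coords[, 1] + 1L]
  expect_gte(mean(got == 1L), 0.95)
  # selecting everything returns every pixel
  all_tab <- drill_down(h, 1, seq_len(h$scales[[2]]$n_points))
  expect_equal(nrow(all_tab$values), h$n_pixels)
  # partitioning the landmarks partitions the pixels
  sel_b <- setdiff(seq_len(h$scales[[2]]$n_points), sel_a)
  tab_b <- drill_down(h, 1, sel_b)
  ids_a <- tab_a$coords[, 1]; ids_b <- tab_b$coords[, 1]
  expect_length(intersect(ids_a, ids_b), 0)
  expect_setequal(c(ids_a, ids_b), 0:(h$n_pixels - 1L))
  expect_error(drill_down(h, 1, integer(0)), "empty")
})
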