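#' k-nearest-neighbor similarity graph over pixels
#'
#' Builds the directed kNN graph on the rows of a pixel table (Euclidean
#' distance on transformed marker values). Edge weights decay with
#' distance: `w_ij = exp(-(d_ij / sigma_i)^2)` with `sigma_i` the mean
#' distance from `i` to its k neighbors (all weights 1 when `sigma_i = 0`,
#' i.e. duplicated rows). Small inputs use an exact search with
#' deterministic (distance, row index) tie-breaking; larger inputs use a
#' kd-tree.
#'
#' @param table a [pixel_table()].
#' @param k neighbor count (default 30); clamped to `n - 1` with a warning
#'   when `k >= n`.
#' @return A `knn_graph` object: list with `neighbors` (`n x k`, 1-based),
#'   `dist`, `weights` (`n x k`), `k`, and the source `table`.
#' @export
build_knn_graph <- function(table, k = 30) {
  stopifnot(inherits(table, "pixel_table"))
  x <- table$values
  n <- nrow(x)
  if (n < 1L) stop("pixel table is empty")
  if (n < 2L) stop("need at least 2 pixels to build a kNN graph")
  if (k >= n) {
    warning(sprintf("k = %d >= n = %d; clamping k to %d", k, n, n - 1L))
    k <- n - 1L
  }
  if (n <= 2048L) {
    d2 <- as.matrix(dist(x))^2
    neighbors <- matrix(0L, n, k)
    dmat <- matrix(0, n, k)
    for (i in seq_len(n)) {
      ord <- order(d2[i, ], seq_len(n))     # ties broken by row index
      ord <- ord[ord != i][seq_len(k)]
      neighbors[i, ] <- ord
      dmat[i, ] <- sqrt(pmax(d2[i, ord], 0))
    }
  } else {
    nn <- RANN::nn2(x, k = k + 1L)
    # drop the self hit per row (or the last column when absent)
    keep <- nn$nn.idx != seq_len(n)
    extra <- rowSums(keep) > k
    keep[extra, k + 1L] <- FALSE
    neighbors <- matrix(t(nn$nn.idx)[t(keep)], n, k, byrow = TRUE)
    dmat <- matrix(t(nn$nn.dists)[t(keep)], n, k, byrow = TRUE)
  }
  sigma <- rowMeans(dmat)
  weights <- matrix(1, n, k)
  pos <- sigma > 0
  weights[pos, ] <- exp(-(dmat[pos, , drop = FALSE] / sigma[pos])^2)
  structure(list(neighbors = neighbors, dist = dmat, weights = weights,
                 k = k, n_nodes = n, table = table),
            class = "knn_graph")
}

#' @export
print.knn_graph <- function(x, ...) {
  cat(sprintf("knn_graph: %d nodes, k = %d\n", x$n_nodes, x$k))
  invisible(x)
}

# cumulative row weights for the C++ walkers (column sweep: fast at any n)
cumulative_weights <- function(weights) {
  out <- weights
  for (j in seq_len(ncol(out))[-1L]) out[, j] <- out[, j - 1L] + out[, j]
  out
}

# given triplet vectors ordered however, keep at most m entries per row,
# preferring larger x (ties -> lower column); returns logical keep mask
# computed fully vectorized (no per-row loops)
triplet_top_m <- function(i, x, j, m) {
  ord <- order(i, -x, j)
  i_ord <- i[ord]
  first <- which(!duplicated(i_ord))
  start <- rep.int(first, diff(c(first, length(i_ord) + 1L)))
  slot <- seq_along(i_ord) - start + 1L
  keep <- logical(length(i))
  keep[ord[slot <= m]] <- TRUE
  keep
}

# argmax per row of a sparse matrix; ties -> lowest column index;
# all-zero rows -> 0
sparse_row_argmax <- function(m) {
  tr <- Matrix::summary(m)
  out <- integer(nrow(m))
  if (nrow(tr)) {
    ord <- order(tr$i, -tr$x, tr$j)
    tr <- tr[ord, , drop = FALSE]
    first <- !duplicated(tr$i)
    out[tr$i[first]] <- tr$j[first]
  }
  out
}

#' Multi-scale landmark hierarchy over pixels
#'
#' Builds an HSNE-style hierarchy: scale 0 indexes every pixel; at each
#' coarser scale, landmarks are nodes whose random-walk visit count exceeds
#' a multiple of the expected count, and each finer point's area-of-influence
#' row is estimated from Monte-Carlo walks absorbed at landmarks. Landmark
#' weights propagate the represented pixel mass, so at every scale they sum
#' to the pixel count. The walk graph of the next scale comes from the
#' strongest area-of-influence overlaps, `t(I) %*% diag(w) %*% I`.
#'
#' @param graph a [build_knn_graph()] result.
#' @param n_scales total number of scales including the data scale
#'   (default 3). The hierarchy is truncated with a warning if a scale
#'   would have fewer than 10 landmarks.
#' @param walk_params list overriding any of `n_walks` (100), `walk_len`
#'   (50), `threshold` (1.5, multiple of the expected visit count),
#'   `n_walks_influence` (100), `max_steps` (500, absorption cap),
#'   `max_influence` (16, influence rows are pruned to this many
#'   strongest landmarks and renormalized — bounds the memory of the
#'   overlap computation at full-ROI scale).
#' @param seed integer seed for all walk randomness.
#' @return An `hsne_hierarchy` object.
#' @export
build_hierarchy <- function(graph, n_scales = 3, walk_params = list(),
                            seed = 1L) {
  stopifnot(inherits(graph, "knn_graph"))
  if (n_scales < 1) stop("n_scales must be >= 1")
  wp <- modifyList(list(n_walks = 100L, walk_len = 50L, threshold = 1.5,
                        n_walks_influence = 100L, max_steps = 500L,
                        max_influence = 16L),
                   walk_params)
  n0 <- graph$n_nodes
  scales <- list(list(n_points = n0, rep_pixel = seq_len(n0),
                      landmark_weight = rep(1, n0)))
  cur_neighbors <- graph$neighbors
  cur_weights <- graph$weights
  cur_n <- n0
  s <- 1L
  while (s < n_scales) {
    cumw <- cumulative_weights(cur_weights)
    visits <- cpp_walk_visits(cur_neighbors - 1L, cumw, wp$n_walks,
                              wp$walk_len, seed + 13 * s)
    expected <- wp$n_walks * wp$walk_len
    landmarks <- which(visits > wp$threshold * expected)
    if (length(landmarks) < 10L) {
      warning(sprintf(
        "scale %d would have %d landmarks (< 10); hierarchy truncated at %d scale(s)",
        s, length(landmarks), s))
      break
    }
    landmark_of <- rep(-1L, cur_n)
    landmark_of[landmarks] <- seq_along(landmarks) - 1L
    tri <- cpp_absorb_walks(cur_neighbors - 1L, cumw, landmark_of,
                            wp$n_walks_influence, wp$max_steps,
                            seed + 13 * s + 7)
    # bound row support: keep each point's strongest landmarks only
    keep <- triplet_top_m(tri$i, tri$x, tri$j, wp$max_influence)
    infl <- Matrix::sparseMatrix(i = tri$i[keep] + 1L, j = tri$j[keep] + 1L,
                                 x = tri$x[keep],
                                 dims = c(cur_n, length(landmarks)))
    rm(tri, keep)
    # points whose walks never reached a landmark: nearest landmark in
    # marker space (deterministic fallback, keeps rows stochastic)
    rs <- Matrix::rowSums(infl)
    if (any(rs == 0)) {
      miss <- which(rs == 0)
      prev_rep <- scales[[s]]$rep_pixel
      land_x <- graph$table$values[prev_rep[landmarks], , drop = FALSE]
      miss_x <- graph$table$values[prev_rep[miss], , drop = FALSE]
      nearest <- RANN::nn2(land_x, miss_x, k = 1L)$nn.idx[, 1L]
      infl <- infl + Matrix::sparseMatrix(i = miss, j = nearest,
                                          x = rep(1, length(miss)),
                                          dims = dim(infl))
      rs[miss] <- 1
    }
    infl <- Matrix::Diagonal(x = 1 / rs) %*% infl
    infl <- methods::as(infl, "CsparseMatrix")
    w_prev <- scales[[s]]$landmark_weight
    w_new <- as.numeric(Matrix::crossprod(infl, w_prev))
    scales[[s + 1L]] <- list(
      n_points = length(landmarks),
      landmark_indices = landmarks,
      influence = infl,
      landmark_weight = w_new,
      rep_pixel = scales[[s]]$rep_pixel[landmarks])
    # next-scale walk graph: strongest area-of-influence overlap neighbors
    # per landmark, from t(I) diag(w) I (computed transiently)
    nl <- length(landmarks)
    k_next <- min(graph$k, nl - 1L)
    nb <- matrix(1L, nl, k_next)
    wt <- matrix(0, nl, k_next)
    overlap <- Matrix::crossprod(infl, Matrix::Diagonal(x = w_prev) %*% infl)
    overlap <- methods::as(overlap, "CsparseMatrix")
    diag(overlap) <- 0
    ovt <- Matrix::summary(overlap)
    rm(overlap)
    pos <- ovt$x > 0
    ovt <- list(i = ovt$i[pos], j = ovt$j[pos], x = ovt$x[pos])
    if (length(ovt$i)) {
      ord <- order(ovt$i, -ovt$x, ovt$j)
      i_ord <- ovt$i[ord]
      first <- which(!duplicated(i_ord))
      start <- rep.int(first, diff(c(first, length(i_ord) + 1L)))
      slot <- seq_along(i_ord) - start + 1L
      keep <- slot <= k_next
      nb[cbind(i_ord[keep], slot[keep])] <- ovt$j[ord][keep]
      wt[cbind(i_ord[keep], slot[keep])] <- ovt$x[ord][keep]
    }
    rm(ovt)
    isolated <- Matrix::rowSums(wt) == 0
    if (any(isolated)) {        # self-loop keeps the walker in place
      nb[isolated, 1L] <- which(isolated)
      wt[isolated, 1L] <- 1
    }
    cur_neighbors <- nb
    cur_weights <- wt
    cur_n <- nl
    s <- s + 1L
  }
  structure(list(scales = scales, n_pixels = n0, k = graph$k,
                 walk_params = wp, seed = seed, table = graph$table),
            class = "hsne_hierarchy")
}

#' @export
print.hsne_hierarchy <- function(x, ...) {
  cat(sprintf("hsne_hierarchy: %d pixels, %d scale(s)\n", x$n_pixels,
              length(x$scales)))
  for (s in seq_along(x$scales)) {
    cat(sprintf("  scale %d: %d points\n", s - 1L, x$scales[[s]]$n_points))
  }
  invisible(x)
}

#' Number of scales in a hierarchy (including the data scale)
#' @param hierarchy an `hsne_hierarchy`.
#' @return integer count of scales; the data scale is scale 0.
#' @export
n_scales <- function(hierarchy) length(hierarchy$scales)

#' Compose influence maps from pixels up to a scale
#'
#' Multiplies the per-scale area-of-influence matrices to obtain the
#' row-stochastic map from every pixel to the landmarks of the requested
#' scale. Scale 0 yields the identity.
#'
#' @param hierarchy an `hsne_hierarchy`.
#' @param scale integer scale index (0 = data scale).
#' @return sparse `n_pixels x n_landmarks` row-stochastic matrix.
#' @export
compose_influence <- function(hierarchy, scale) {
  check_scale(hierarchy, scale)
  out <- Matrix::Diagonal(hierarchy$n_pixels)
  if (scale >= 1) {
    for (s in seq_len(scale)) {
      out <- out %*% hierarchy$scales[[s + 1L]]$influence
    }
  }
  methods::as(out, "CsparseMatrix")
}

check_scale <- function(hierarchy, scale) {
  if (scale < 0 || scale > length(hierarchy$scales) - 1L) {
    stop(sprintf("scale %d does not exist (hierarchy has scales 0..%d)",
                 scale, length(hierarchy$scales) - 1L))
  }
  invisible(TRUE)
}

#' Hard pixel-to-landmark assignment at a scale
#'
#' Argmax of the composed influence per pixel, ties broken by the lowest
#' landmark index; pixels carrying no influence mass get 0.
#'
#' @inheritParams compose_influence
#' @return integer vector (length `n_pixels`) of 1-based landmark indices
#'   at `scale`, 0 where no mass flows.
#' @export
hard_assignment <- function(hierarchy, scale) {
  check_scale(hierarchy, scale)
  if (scale == 0) return(seq_len(hierarchy$n_pixels))
  sparse_row_argmax(compose_influence(hierarchy, scale))
}

# joint t-SNE probability matrix from asymmetric conditional similarities
# (rows of `cond` need not be normalized); point weights enter with
# multiplicity semantics: P_ij propto w_i w_j (p_{j|i} + p_{i|j})
joint_probabilities <- function(cond, weights) {
  rs <- Matrix::rowSums(cond)
  rs[rs == 0] <- 1
  p <- Matrix::Diagonal(x = 1 / rs) %*% cond
  pj <- p + Matrix::t(p)
  pj <- Matrix::Diagonal(x = weights) %*% pj %*% Matrix::Diagonal(x = weights)
  as.matrix(pj / sum(pj))
}

# perplexity-calibrated conditional p_{j|i} on kNN distances (dense n x k)
perplexity_conditionals <- function(neighbors, dmat, perplexity) {
  n <- nrow(neighbors)
  k <- ncol(neighbors)
  perplexity <- min(perplexity, max(1, (n - 1) / 3))
  target <- log(perplexity)
  pvals <- matrix(0, n, k)
  for (i in seq_len(n)) {
    d2 <- dmat[i, ]^2
    beta_lo <- 0; beta_hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-d2 * beta)
      sw <- sum(w)
      if (sw <= 0) { h <- 0 } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) {          # too flat -> increase beta
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta + beta_lo) / 2
      }
    }
    w <- exp(-d2 * beta)
    sw <- sum(w)
    pvals[i, ] <- if (sw > 0) w / sw else rep(1 / k, k)
  }
  Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.integer(neighbors),
                       x = as.numeric(pvals), dims = c(n, n))
}

#' Embed one scale of the hierarchy in 2-D
#'
#' Runs an exact t-SNE on the points of the requested scale. Similarities
#' are perplexity-calibrated Gaussian conditionals on the scale's kNN
#' graph (at landmark scales, over the landmarks' representative marker
#' profiles), and each point's weight — the pixel mass a landmark
#' represents — scales its attractive forces, so heavy landmarks anchor
#' denser islands. Identical seed and parameters give bit-identical
#' coordinates.
#'
#' @param hierarchy an `hsne_hierarchy`.
#' @param scale scale to embed (0 = all pixels).
#' @param params list overriding `perplexity` (30), `iterations` (1000),
#'   `exaggeration` (12), `exaggeration_iters` (250), `eta` (200),
#'   `weight_power` (0.5; landmark masses enter the objective as
#'   `weight^weight_power` — the square-root default keeps very heavy
#'   background landmarks from absorbing all attraction mass while
#'   preserving the mass ordering).
#' @param seed integer seed for the random initial layout.
#' @return An `embedding` object: list with `points` (`P x 2` matrix),
#'   `scale`, `seed`, `params`, `weights`.
#' @export
embed_scale <- function(hierarchy, scale, params = list(), seed = 1L) {
  check_scale(hierarchy, scale)
  pr <- modifyList(list(perplexity = 30, iterations = 1000,
                        exaggeration = 12, exaggeration_iters = 250,
                        eta = 200, weight_power = 0.5), params)
  sc <- hierarchy$scales[[scale + 1L]]
  n <- sc$n_points
  weights <- sc$landmark_weight
  if (n < 2L) {
    warning("fewer than 2 points at this scale; returning a single-point layout")
    pts <- matrix(0, n, 2)
    return(structure(list(points = pts, scale = scale, seed = seed,
                          params = pr, weights = weights^pr$weight_power,
                          landmark_weight = weights),
                     class = "embedding"))
  }
  tab <- hierarchy$table
  sub <- if (scale == 0) tab else subset_pixel_table(tab, sc$rep_pixel)
  k_embed <- min(max(hierarchy$k, ceiling(3 * pr$perplexity)), n - 1L)
  g <- build_knn_graph(sub, k = k_embed)
  cond <- perplexity_conditionals(g$neighbors, g$dist, pr$perplexity)
  w_eff <- weights^pr$weight_power
  P <- joint_probabilities(cond, w_eff)
  Y0 <- with_private_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  pts <- cpp_tsne(P, w_eff / mean(w_eff), Y0,
                  as.integer(pr$iterations), pr$exaggeration,
                  as.integer(pr$exaggeration_iters), pr$eta)
  structure(list(points = pts, scale = scale, seed = seed, params = pr,
                 weights = w_eff, landmark_weight = weights),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d points at scale %d (seed %d)\n",
              nrow(x$points), x$scale, x$seed))
  invisible(x)
}

#' Drill down into a landmark selection
#'
#' Returns the pixel table of all scale-0 pixels whose strongest composed
#' influence flows into the selected landmarks — the zoom-in step that
#' feeds a fresh analysis of a gated subset (e.g. tissue pixels, then
#' CD45+/dim pixels).
#'
#' @param hierarchy an `hsne_hierarchy`.
#' @param scale scale of the selection.
#' @param selected integer vector of 1-based landmark indices at `scale`.
#' @return A [pixel_table()] of the captured pixels.
#' @export
drill_down <- function(hierarchy, scale, selected) {
  check_scale(hierarchy, scale)
  if (!length(selected)) stop("selection is empty")
  n_at <- hierarchy$scales[[scale + 1L]]$n_points
  if (any(selected < 1L) || any(selected > n_at)) {
    stop("selected landmark indices out of range for this scale")
  }
  assign <- hard_assignment(hierarchy, scale)
  pix <- which(assign %in% selected)
  if (!length(pix)) stop("no pixels flow into the selected landmarks")
  subset_pixel_table(hierarchy$table, pix)
}
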