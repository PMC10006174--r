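#' Cluster a 2-D embedding by weighted Gaussian mean-shift
#'
#' Density modes of the embedding define clusters, mirroring how gates are
#' drawn around islands in a t-SNE map. Every point ascends the weighted
#' kernel-density gradient until convergence; converged positions within
#' half a bandwidth of each other are merged into one mode. The procedure
#' is deterministic and invariant to point order.
#'
#' @param embedding an [embed_scale()] result, or a `P x 2` matrix.
#' @param weights optional non-negative point weights (landmark weights by
#'   default when an embedding object is given).
#' @param bandwidth kernel bandwidth in embedding units; default 5% of the
#'   embedding bounding-box diagonal.
#' @param max_iter,tol mean-shift iteration controls.
#' @return A `cluster_labels` object: list with `labels` (0-based cluster
#'   per point), `n_clusters`, `modes` (cluster centers), `bandwidth`.
#' @export
cluster_embedding <- function(embedding, weights = NULL, bandwidth = NULL,
                              max_iter = 200, tol = 1e-6) {
  pts <- if (inherits(embedding, "embedding")) embedding$points
         else as.matrix(embedding)
  n <- nrow(pts)
  if (n < 1L) stop("embedding has no points")
  if (is.null(weights)) {
    weights <- if (inherits(embedding, "embedding")) embedding$weights
               else rep(1, n)
  }
  if (n == 1L) {
    return(structure(list(labels = 0L, n_clusters = 1L, modes = pts,
                          bandwidth = bandwidth),
                     class = "cluster_labels"))
  }
  if (is.null(bandwidth)) {
    rng <- apply(pts, 2, range)
    bandwidth <- 0.05 * sqrt(sum((rng[2, ] - rng[1, ])^2))
    if (bandwidth <= 0) bandwidth <- 1e-6
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  h2 <- bandwidth^2
  cur <- pts
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(cur^2), rowSums(pts^2), "+") - 2 * cur %*% t(pts)
    kern <- exp(-d2 / (2 * h2)) * rep(weights, each = n)
    denom <- rowSums(kern)
    denom[denom == 0] <- 1
    nxt <- (kern %*% pts) / denom
    shift <- max(sqrt(rowSums((nxt - cur)^2)))
    cur <- nxt
    if (shift < tol * bandwidth) break
  }
  # merge converged positions within bandwidth/2 (connected components)
  md <- as.matrix(dist(cur))
  adj <- md <= bandwidth / 2
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  # stable numbering: clusters ordered by their mode position (x, then y)
  modes <- t(vapply(seq_len(cid), function(g) {
    colMeans(cur[comp == g, , drop = FALSE])
  }, numeric(2)))
  ord <- order(modes[, 1], modes[, 2])
  renum <- match(seq_len(cid), ord)
  labels <- renum[comp] - 1L
  structure(list(labels = labels, n_clusters = cid,
                 modes = modes[ord, , drop = FALSE], bandwidth = bandwidth),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf("cluster_labels: %d points in %d cluster(s)\n",
              length(x$labels), x$n_clusters))
  invisible(x)
}

#' Expand landmark cluster labels to every pixel
#'
#' Back-propagates labels down the hierarchy: each pixel receives the label
#' of the landmark holding its strongest composed influence (argmax, ties
#' to the lowest landmark index); pixels carrying no influence mass stay
#' background (0).
#'
#' @param hierarchy an `hsne_hierarchy`.
#' @param scale scale at which `landmark_labels` are defined.
#' @param landmark_labels a [cluster_embedding()] result (or integer vector
#'   of 0-based labels, -1 for unassigned) covering all landmarks at
#'   `scale`.
#' @return A `pixel_labeling` object: list with `label_map` (`H x W`
#'   integer raster; 0 background, k >= 1 class) and `class_names`
#'   (label -> name, initially cluster numbers).
#' @export
expand_to_pixels <- function(hierarchy, scale, landmark_labels) {
  check_scale(hierarchy, scale)
  labels <- if (inherits(landmark_labels, "cluster_labels")) {
    landmark_labels$labels
  } else as.integer(landmark_labels)
  n_at <- hierarchy$scales[[scale + 1L]]$n_points
  if (length(labels) != n_at) {
    stop(sprintf("labels cover %d landmarks but scale %d has %d points",
                 length(labels), scale, n_at))
  }
  assign <- hard_assignment(hierarchy, scale)
  tab <- hierarchy$table
  label_map <- matrix(0L, tab$image_dim[1], tab$image_dim[2])
  pix_label <- ifelse(assign > 0L, labels[pmax(assign, 1L)] + 1L, 0L)
  pix_label[pix_label < 0L] <- 0L          # -1 (unassigned) -> background
  label_map[cbind(tab$coords[, 1] + 1L, tab$coords[, 2] + 1L)] <- pix_label
  classes <- sort(unique(pix_label[pix_label > 0L]))
  structure(list(label_map = label_map,
                 class_names = setNames(paste0("cluster_", classes - 1L),
                                        classes)),
            class = "pixel_labeling")
}

#' @export
print.pixel_labeling <- function(x, ...) {
  tab <- table(x$label_map[x$label_map > 0])
  cat(sprintf("pixel_labeling: %d x %d, %d class(es)\n",
              nrow(x$label_map), ncol(x$label_map), length(x$class_names)))
  for (l in names(x$class_names)) {
    cat(sprintf("  %s (label %s): %d px\n", x$class_names[[l]], l,
                if (l %in% names(tab)) tab[[l]] else 0L))
  }
  invisible(x)
}

#' Cell-type signature table
#'
#' Marker requirement rules in the notation of manual gating, e.g. a T cell
#' is CD3+CD7+ and an ILC is CD3-CD7+. Matching is ordered: the first
#' signature whose requirements all hold names a cluster.
#'
#' @param cell_type character vector of unique type names.
#' @param positive list of character vectors: markers required positive.
#' @param negative list of character vectors: markers required negative.
#' @return A `signature_table` object.
#' @export
signature_table <- function(cell_type, positive, negative = NULL) {
  if (!length(cell_type)) stop("signature table is empty")
  if (anyDuplicated(cell_type)) stop("cell-type names must be unique")
  if (is.null(negative)) negative <- rep(list(character(0)), length(cell_type))
  stopifnot(length(positive) == length(cell_type),
            length(negative) == length(cell_type))
  structure(list(cell_type = as.character(cell_type),
                 positive = positive, negative = negative),
            class = "signature_table")
}

#' Read a signature table from YAML
#'
#' Expects a mapping of cell-type name to lists `positive` and (optional)
#' `negative` of marker names, in priority order.
#'
#' @param path YAML file.
#' @return A [signature_table()].
#' @export
read_signatures <- function(path) {
  y <- yaml::read_yaml(path)
  signature_table(names(y),
                  lapply(y, function(e) as.character(e$positive)),
                  lapply(y, function(e)
                    if (is.null(e$negative)) character(0)
                    else as.character(e$negative)))
}

#' Default immune/structural signature set
#'
#' The phenotype rules resolvable by pixel analysis of the immune panel:
#' T cell (CD3+CD7+), ILC (CD3-CD7+), B cell (CD20+HLA-DR+), macrophage
#' (CD163+HLA-DR+), Lin-HLA-DR+ myeloid (CD3-CD7-CD20-CD163-HLA-DR+),
#' epithelium (E-cadherin+), stroma (vimentin+).
#'
#' @return A [signature_table()].
#' @export
default_signatures <- function() {
  signature_table(
    cell_type = c("T cell", "ILC", "B cell", "macrophage", "myeloid",
                  "epithelium", "stroma"),
    positive = list(c("CD3", "CD7"), "CD7", c("CD20", "HLA-DR"),
                    c("CD163", "HLA-DR"), "HLA-DR", "E-cadherin",
                    "vimentin"),
    negative = list(character(0), "CD3", character(0), character(0),
                    c("CD3", "CD7", "CD20", "CD163"), character(0),
                    character(0)))
}

#' Merge clusters that share a cell-type name
#'
#' Mean-shift routinely splits one phenotype into several embedding
#' islands; after [assign_cell_types()] those clusters carry the same
#' name. This collapses them into one rendered class per name, which is
#' how a <= 9 color overlay is produced from a finer clustering.
#'
#' @param labeling a named `pixel_labeling` (after [assign_cell_types()]).
#' @param drop_unassigned send `"unassigned"` pixels to background
#'   (default `FALSE`).
#' @return A `pixel_labeling` with one label per distinct class name,
#'   numbered in order of first appearance.
#' @export
merge_labels_by_name <- function(labeling, drop_unassigned = FALSE) {
  stopifnot(inherits(labeling, "pixel_labeling"))
  old_labels <- as.integer(names(labeling$class_names))
  nms <- unname(labeling$class_names)
  uniq <- unique(nms)
  if (drop_unassigned) uniq <- setdiff(uniq, "unassigned")
  new_of_old <- match(nms, uniq)          # NA -> background
  new_of_old[is.na(new_of_old)] <- 0L
  lm <- labeling$label_map
  out <- matrix(0L, nrow(lm), ncol(lm))
  for (i in seq_along(old_labels)) {
    if (new_of_old[i] > 0L) out[lm == old_labels[i]] <- new_of_old[i]
  }
  structure(list(label_map = out,
                 class_names = setNames(uniq, seq_along(uniq))),
            class = "pixel_labeling")
}

#' Per-marker positivity thresholds over a pixel table
#'
#' A marker is "positive" above its `positive` quantile of the analyzed
#' pixels' (transformed) intensities and "dim" between the `dim` and
#' `positive` quantiles — the operational version of +/dim gates.
#'
#' @param table a [pixel_table()].
#' @param positive positivity quantile (default 0.6).
#' @param dim lower bound of the dim range (default 0.3).
#' @return list with numeric vectors `positive` and `dim`, one threshold
#'   per marker.
#' @export
positivity_thresholds <- function(table, positive = 0.6, dim = 0.3) {
  stopifnot(inherits(table, "pixel_table"))
  list(positive = apply(table$values, 2, quantile, probs = positive,
                        names = FALSE),
       dim = apply(table$values, 2, quantile, probs = dim, names = FALSE))
}

#' Name clusters from marker signatures
#'
#' For each cluster, the member-pixel median of every marker is compared to
#' the per-marker positivity threshold (a quantile over all analyzed
#' pixels). The first signature whose positive markers are all above and
#' negative markers all at-or-below threshold names the cluster; clusters
#' matching nothing are kept as `"unassigned"`. If a cluster satisfies
#' several signatures the first in table order wins and a warning reports
#' the alternatives.
#'
#' @param labeling a [expand_to_pixels()] result.
#' @param table the [pixel_table()] the labeling derives from (pixel rows
#'   must correspond to the labeling's raster coordinates).
#' @param signatures a [signature_table()].
#' @param positivity_quantile quantile defining marker positivity
#'   (default 0.6).
#' @return The labeling with `class_names` replaced by cell-type names.
#' @export
assign_cell_types <- function(labeling, table, signatures,
                              positivity_quantile = 0.6) {
  stopifnot(inherits(labeling, "pixel_labeling"),
            inherits(table, "pixel_table"),
            inherits(signatures, "signature_table"))
  if (!length(signatures$cell_type)) stop("signature table is empty")
  sig_markers <- unique(c(unlist(signatures$positive),
                          unlist(signatures$negative)))
  unknown <- setdiff(sig_markers, table$marker_names)
  if (length(unknown)) {
    stop("signature markers absent from the table: ",
         paste(unknown, collapse = ", "))
  }
  thr <- positivity_thresholds(table, positive = positivity_quantile)$positive
  names(thr) <- table$marker_names
  pix_label <- labeling$label_map[cbind(table$coords[, 1] + 1L,
                                        table$coords[, 2] + 1L)]
  classes <- sort(unique(pix_label[pix_label > 0L]))
  new_names <- setNames(character(length(classes)), classes)
  for (cl in classes) {
    members <- table$values[pix_label == cl, , drop = FALSE]
    med <- apply(members, 2, median)
    is_pos <- med > thr
    matches <- which(vapply(seq_along(signatures$cell_type), function(i) {
      all(is_pos[signatures$positive[[i]]]) &&
        !any(is_pos[signatures$negative[[i]]])
    }, logical(1)))
    if (!length(matches)) {
      new_names[[as.character(cl)]] <- "unassigned"
    } else {
      if (length(matches) > 1L) {
        warning(sprintf("cluster %d matches several signatures (%s); using '%s'",
                        cl, paste(signatures$cell_type[matches],
                                  collapse = ", "),
                        signatures$cell_type[matches[1L]]))
      }
      new_names[[as.character(cl)]] <- signatures$cell_type[matches[1L]]
    }
  }
  labeling$class_names <- new_names
  labeling
}
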