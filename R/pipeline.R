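#' Assemble and validate a pipeline run configuration
#'
#' A run is driven either by a synthetic spec (`spec`) or by files on disk
#' (`image` + `panel`, optionally `roi_mask` + `groups`). All referenced
#' files must exist at validation time. Every random stage derives its
#' stream from the single `seed`.
#'
#' @param out_dir output directory (created if missing).
#' @param spec optional [synthetic_spec()] object or YAML path.
#' @param image,panel paths to a multichannel TIFF and its panel TSV
#'   (ignored when `spec` is given).
#' @param roi_mask,groups optional label-mask TIFF and group TSV.
#' @param signatures a [signature_table()] or YAML path (default
#'   [default_signatures()]).
#' @param markers similarity markers for the embedding (default: panel).
#' @param cofactor,percentile preprocessing parameters (defaults 5, 98).
#' @param k,scales hierarchy parameters (defaults 30, 2).
#' @param embed_params list passed to [embed_scale()].
#' @param bandwidth mean-shift bandwidth (`NULL` = 5% of embedding
#'   diagonal).
#' @param positivity_quantile marker positivity quantile (default 0.6).
#' @param marker_a,marker_b quantified marker pair (defaults CD161, CD69).
#' @param direction Mann-Whitney direction for group LF (default
#'   `"greater"`).
#' @param seed master seed.
#' @return A validated `run_config` object.
#' @export
run_config <- function(out_dir, spec = NULL, image = NULL, panel = NULL,
                       roi_mask = NULL, groups = NULL,
                       signatures = default_signatures(), markers = NULL,
                       cofactor = 5, percentile = 98, k = 30, scales = 2,
                       embed_params = list(), bandwidth = NULL,
                       positivity_quantile = 0.6, marker_a = "CD161",
                       marker_b = "CD69", direction = "greater", seed = 1L) {
  if (is.null(spec)) {
    if (is.null(image) || is.null(panel)) {
      stop("provide either a synthetic spec or image + panel paths")
    }
    for (f in c(image, panel, roi_mask, groups)) {
      if (!is.null(f) && !file.exists(f)) stop("file not found: ", f)
    }
  } else if (is.character(spec)) {
    if (!file.exists(spec)) stop("file not found: ", spec)
    spec <- read_synthetic_spec(spec)
  }
  if (is.character(signatures)) {
    if (!file.exists(signatures)) stop("file not found: ", signatures)
    signatures <- read_signatures(signatures)
  }
  cfg <- list(out_dir = out_dir, spec = spec, image = image, panel = panel,
              roi_mask = roi_mask, groups = groups, signatures = signatures,
              markers = markers, cofactor = cofactor,
              percentile = percentile, k = k, scales = scales,
              embed_params = embed_params, bandwidth = bandwidth,
              positivity_quantile = positivity_quantile,
              marker_a = marker_a, marker_b = marker_b,
              direction = direction, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  digest::digest(config[setdiff(names(config), "out_dir")], algo = "sha1")
}

pip_log <- function(con, level, fmt, ...) {
  msg <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 level, sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
  invisible(NULL)
}

#' Run the full pixel-phenotyping pipeline
#'
#' Executes every stage in order — image acquisition (synthetic or from
#' disk), preprocessing, hierarchy construction, embedding of the top
#' scale, mean-shift clustering, label expansion, cell-type assignment,
#' overlay rendering and double-positive quantification — and writes all
#' artifacts with provenance metadata (config hash, seed, package version)
#' into `config$out_dir`. Re-running with an identical config reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `table`, `hierarchy`, `embedding`,
#'   `clusters`, `labeling`, `overlay`, `quantification`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "run.log")
  con <- file(logfile, open = "w")
  on.exit(close(con), add = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  stage <- function(name, expr) {
    pip_log(con, "INFO", "stage %s", name)
    tryCatch(expr, error = function(e) {
      pip_log(con, "ERROR", "stage %s failed: %s", name,
              conditionMessage(e))
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  acquired <- stage("acquire", {
    if (!is.null(config$spec)) {
      gen <- generate_multiplex_image(config$spec)
      write_multichannel_tiff(gen$stack,
                              file.path(config$out_dir, "image.tiff"))
      write_label_tiff(gen$truth$label_map,
                       file.path(config$out_dir, "truth_labels.tiff"))
      list(stack = gen$stack, rois = gen$truth$roi_set)
    } else {
      pan <- read_panel(config$panel)
      rois <- if (!is.null(config$roi_mask)) {
        read_roi_mask(config$roi_mask, config$groups)
      }
      list(stack = read_multichannel_tiff(config$image, pan), rois = rois)
    }
  })
  stack <- acquired$stack
  rois <- acquired$rois

  table <- stage("preprocess", {
    flatten(stack, markers = config$markers, cofactor = config$cofactor,
            percentile = config$percentile)
  })

  hierarchy <- stage("hierarchy", {
    g <- build_knn_graph(table, k = config$k)
    build_hierarchy(g, n_scales = config$scales, seed = seed + 101L)
  })

  top <- n_scales(hierarchy) - 1L
  embedding <- stage("embed", {
    embed_scale(hierarchy, top, params = config$embed_params,
                seed = seed + 202L)
  })
  utils::write.table(
    data.frame(x = embedding$points[, 1], y = embedding$points[, 2],
               weight = embedding$weights),
    file.path(config$out_dir, "embedding.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  clusters <- stage("cluster", {
    cluster_embedding(embedding, bandwidth = config$bandwidth)
  })

  labeling <- stage("gate", {
    lab <- expand_to_pixels(hierarchy, top, clusters)
    # only signatures whose markers were measured can be evaluated
    sigs <- config$signatures
    usable <- vapply(seq_along(sigs$cell_type), function(i) {
      all(c(sigs$positive[[i]], sigs$negative[[i]]) %in% table$marker_names)
    }, logical(1))
    if (!any(usable)) {
      pip_log(con, "WARN",
              "no signature is evaluable on this panel; keeping cluster ids")
      lab
    } else {
      if (!all(usable)) {
        pip_log(con, "WARN", "skipping signatures needing absent markers: %s",
                paste(sigs$cell_type[!usable], collapse = ", "))
      }
      sigs <- signature_table(sigs$cell_type[usable], sigs$positive[usable],
                              sigs$negative[usable])
      assign_cell_types(lab, table, sigs,
                        positivity_quantile = config$positivity_quantile)
    }
  })
  write_label_tiff(labeling$label_map,
                   file.path(config$out_dir, "class_labels.tiff"))

  overlay <- stage("render", {
    # one rendered class per cell-type name; then enforce the 9-color cap
    named <- merge_labels_by_name(labeling)
    if (length(named$class_names) > 9L) {
      named <- merge_labels_by_name(labeling, drop_unassigned = TRUE)
    }
    if (length(named$class_names) > 9L) {
      keep <- names(head(named$class_names, 9L))
      lm <- named$label_map
      lm[!(lm %in% as.integer(keep))] <- 0L
      named$label_map <- lm
      named$class_names <- named$class_names[keep]
      pip_log(con, "WARN",
              "more than 9 named classes; rendering the first 9")
    }
    ov <- backproject(named, default_palette())
    write_overlay(file.path(config$out_dir, "overlay.png"), ov)
    ov
  })

  quantification <- stage("quantify", {
    if (is.null(rois) || !length(rois$regions)) {
      pip_log(con, "WARN", "no ROI set available; skipping quantification")
      NULL
    } else {
      res <- compare_groups(stack, config$marker_a, config$marker_b, rois,
                            direction = config$direction)
      write_quantification(res,
                           file.path(config$out_dir, "quantification.tsv"))
      res
    }
  })

  provenance <- list(config_hash = hash, seed = seed,
                     package_version = as.character(
                       utils::packageVersion("pixplore")),
                     scales = n_scales(hierarchy),
                     n_pixels = nrow(table$values))
  yaml::write_yaml(provenance, file.path(config$out_dir, "provenance.yaml"))
  pip_log(con, "INFO", "run complete (config %s)", hash)
  invisible(list(table = table, hierarchy = hierarchy,
                 embedding = embedding, clusters = clusters,
                 labeling = labeling, overlay = overlay,
                 quantification = quantification, provenance = provenance))
}
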