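#' Marker panel
#'
#' A marker panel binds raster channels to metal tags and marker names, as
#' in the antibody panel tables that accompany an IMC acquisition.
#'
#' @param channel_index integer vector of 0-based channel indices; must be
#'   unique and contiguous from 0.
#' @param metal_tag character vector of metal labels (e.g. `"Yb176"`).
#' @param marker_name character vector of unique marker names (e.g.
#'   `"CD45"`).
#' @return A `marker_panel` object: a data.frame with columns
#'   `channel_index`, `metal_tag`, `marker_name`.
#' @examples
#' marker_panel(0:2, c("Y89", "In115", "Pr141"), c("CD45", "CD3", "CD20"))
#' @export
marker_panel <- function(channel_index, metal_tag, marker_name) {
  channel_index <- as.integer(channel_index)
  marker_name <- as.character(marker_name)
  metal_tag <- as.character(metal_tag)
  n <- length(channel_index)
  if (length(metal_tag) != n || length(marker_name) != n) {
    stop("channel_index, metal_tag and marker_name must have equal length")
  }
  if (n == 0L) stop("a marker panel needs at least one entry")
  if (!identical(sort(channel_index), 0:(n - 1L))) {
    stop("channel indices must be unique and contiguous from 0")
  }
  if (anyDuplicated(marker_name)) {
    stop("marker names must be unique: ",
         paste(unique(marker_name[duplicated(marker_name)]), collapse = ", "))
  }
  out <- data.frame(channel_index = channel_index, metal_tag = metal_tag,
                    marker_name = marker_name, stringsAsFactors = FALSE)
  out <- out[order(out$channel_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Read a marker panel table
#'
#' Reads a tab-separated table with columns `channel_index`, `metal_tag`
#' and `marker_name`.
#'
#' @param path path to a TSV file.
#' @return A [marker_panel()].
#' @export
read_panel <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("channel_index", "metal_tag", "marker_name")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("panel table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  marker_panel(tab$channel_index, tab$metal_tag, tab$marker_name)
}

#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "marker_panel"))
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Multichannel image stack
#'
#' The in-memory container for a multiplexed image: an `H x W x C`
#' non-negative array bound to a [marker_panel()]. One pixel corresponds to
#' a square of side `pixel_size` microns (1 by default, the IMC raster).
#'
#' @param data numeric `H x W x C` array (or `H x W` matrix for a single
#'   channel); all values must be non-negative.
#' @param panel a [marker_panel()] with exactly `C` entries.
#' @param pixel_size physical edge length of one pixel in microns.
#' @return A `channel_stack` object (list with elements `data`, `panel`,
#'   `pixel_size`).
#' @export
channel_stack <- function(data, panel, pixel_size = 1) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be an H x W x C array")
  }
  if (any(data < 0)) stop("channel intensities must be non-negative")
  if (!inherits(panel, "marker_panel")) stop("panel must be a marker_panel")
  if (dim(data)[3L] != nrow(panel)) {
    stop(sprintf("channel count mismatch: image has %d channels, panel has %d",
                 dim(data)[3L], nrow(panel)))
  }
  dimnames(data) <- list(NULL, NULL, panel$marker_name)
  structure(list(data = data, panel = panel, pixel_size = pixel_size),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("channel_stack: %d x %d pixels, %d channels (%.3g um/px)\n",
              d[1], d[2], d[3], x$pixel_size))
  cat("markers:", paste(x$panel$marker_name, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel as a matrix
#'
#' @param stack a [channel_stack()].
#' @param marker marker name present in the panel.
#' @return `H x W` numeric matrix.
#' @export
get_channel <- function(stack, marker) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!marker %in% stack$panel$marker_name) {
    stop("unknown marker: ", marker)
  }
  stack$data[, , marker, drop = TRUE]
}

#' Read a multichannel TIFF into a channel stack
#'
#' Accepts both the plane-per-page layout (one grayscale page per channel)
#' and a single page with an interleaved sample axis. Integer pixel data are
#' promoted to doubles on their native count scale.
#'
#' @param path path to a TIFF file.
#' @param panel [marker_panel()] naming the channels in file order.
#' @param pixel_size microns per pixel edge (default 1).
#' @return A [channel_stack()].
#' @export
read_multichannel_tiff <- function(path, panel, pixel_size = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  planes <- list()
  for (p in pages) {
    if (length(dim(p)) == 3L) {
      for (k in seq_len(dim(p)[3L])) planes[[length(planes) + 1L]] <- p[, , k]
    } else {
      planes[[length(planes) + 1L]] <- p
    }
  }
  if (length(planes) != nrow(panel)) {
    stop(sprintf("channel count mismatch: file has %d channels, panel has %d",
                 length(planes), nrow(panel)))
  }
  h <- nrow(planes[[1L]]); w <- ncol(planes[[1L]])
  data <- array(0, dim = c(h, w, length(planes)))
  for (k in seq_along(planes)) data[, , k] <- as.numeric(planes[[k]])
  channel_stack(data, panel, pixel_size = pixel_size)
}

#' Write a channel stack as a multi-page 16-bit TIFF
#'
#' One grayscale page per channel, in panel order, stored as 16-bit
#' unsigned integers — the native IMC export depth. Integer counts in
#' `[0, 65535]` round-trip exactly; fractional intensities are rounded to
#' the nearest count.
#'
#' @param stack a [channel_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  if (max(stack$data) > 65535) {
    stop("intensities exceed the 16-bit range (65535)")
  }
  planes <- lapply(seq_len(dim(stack$data)[3L]), function(k) {
    round(stack$data[, , k, drop = TRUE]) / 65535
  })
  tiff::writeTIFF(planes, path, bits.per.sample = 16L,
                  reduce = FALSE, compression = "none")
  invisible(path)
}

#' Write / read an integer label-mask TIFF
#'
#' Label maps (class assignments, ROI masks) are stored as single-page
#' 16-bit integer TIFFs; labels in `[0, 65535]` round-trip exactly.
#'
#' @param label_map `H x W` integer matrix (0 = background).
#' @param path file path.
#' @return `write_label_tiff` returns `path` invisibly; `read_label_tiff`
#'   returns the `H x W` integer matrix.
#' @export
write_label_tiff <- function(label_map, path) {
  if (min(label_map) < 0 || max(label_map) > 65535) {
    stop("labels must lie in [0, 65535]")
  }
  m <- label_map
  storage.mode(m) <- "double"
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, reduce = FALSE,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  m
}

#' Region-of-interest set
#'
#' Named, group-tagged boolean masks used for quantification, e.g. the
#' lymphoid-follicle ("LF") boxes versus equal-area "non-LF" boxes.
#'
#' @param regions a list of regions, each a list with elements `name`
#'   (unique text), `mask` (`H x W` logical matrix) and `group` (text tag).
#' @return A `roi_set` object.
#' @export
roi_set <- function(regions) {
  if (length(regions)) {
    nms <- vapply(regions, function(r) r$name, character(1))
    if (anyDuplicated(nms)) stop("region names must be unique")
    dims <- vapply(regions, function(r) dim(r$mask), integer(2))
    if (length(regions) > 1L && !all(dims == dims[, 1L])) {
      stop("all region masks must share the same dimensions")
    }
    for (r in regions) {
      if (!is.logical(r$mask)) stop("region masks must be logical matrices")
    }
  }
  structure(list(regions = regions), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set with %d regions\n", length(x$regions)))
  for (r in x$regions) {
    cat(sprintf("  %s [%s]: %d px\n", r$name, r$group, sum(r$mask)))
  }
  invisible(x)
}

#' @export
length.roi_set <- function(x) length(x$regions)

#' Groups of an ROI set
#' @param rois a [roi_set()].
#' @return character vector of group tags, one per region.
#' @export
roi_groups <- function(rois) {
  vapply(rois$regions, function(r) r$group, character(1))
}

#' Read a label-mask TIFF into an ROI set
#'
#' Each nonzero integer label in the mask becomes one region; the group
#' table maps labels to region names and group tags (such as `"LF"` and
#' `"non-LF"`).
#'
#' @param path path to a label-mask TIFF (integer labels).
#' @param group_table data.frame with columns `label`, `name`, `group`; or a
#'   path to a TSV file with those columns.
#' @return A [roi_set()]; empty if the mask contains no nonzero labels.
#' @export
read_roi_mask <- function(path, group_table) {
  lab <- read_label_tiff(path)
  if (is.character(group_table)) {
    group_table <- read.delim(group_table, stringsAsFactors = FALSE)
  }
  need <- c("label", "name", "group")
  if (!all(need %in% names(group_table))) {
    stop("group table needs columns: ", paste(need, collapse = ", "))
  }
  labels_present <- sort(unique(lab[lab != 0L]))
  unknown <- setdiff(labels_present, group_table$label)
  if (length(unknown)) {
    stop("labels present in mask but absent from group table: ",
         paste(unknown, collapse = ", "))
  }
  regions <- lapply(labels_present, function(l) {
    row <- group_table[match(l, group_table$label), ]
    list(name = as.character(row$name), mask = lab == l,
         group = as.character(row$group))
  })
  roi_set(regions)
}

# roi_set -> single integer label mask (regions must be disjoint)
roi_label_map <- function(rois, dim_hw) {
  lab <- matrix(0L, dim_hw[1], dim_hw[2])
  for (i in seq_along(rois$regions)) {
    m <- rois$regions[[i]]$mask
    if (any(lab[m] != 0L)) stop("overlapping ROI masks cannot be serialized")
    lab[m] <- i
  }
  lab
}

#' Write an RGB overlay losslessly
#'
#' Writes an 8-bit RGB raster as PNG (default) or uncompressed TIFF; either
#' round-trips every pixel byte exactly.
#'
#' @param path output path; extension `.png` or `.tif`/`.tiff`.
#' @param rgb_image `H x W x 3` numeric array with values in `[0, 255]` (or
#'   integer bytes).
#' @return `path`, invisibly.
#' @export
write_overlay <- function(path, rgb_image) {
  if (!(is.array(rgb_image) && length(dim(rgb_image)) == 3L &&
        dim(rgb_image)[3L] == 3L)) {
    stop("rgb_image must be an H x W x 3 array")
  }
  if (any(rgb_image < 0) || any(rgb_image > 255)) {
    stop("rgb_image values must lie in [0, 255]")
  }
  scaled <- rgb_image / 255
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      tiff::writeTIFF(scaled, path, bits.per.sample = 8L,
                      compression = "none")
    } else {
      png::writePNG(scaled, path)
    }
    TRUE
  }, error = function(e) stop("cannot write overlay to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read an overlay written by [write_overlay()]
#' @param path path to the PNG/TIFF overlay.
#' @return `H x W x 3` numeric array of bytes in `[0, 255]`.
#' @export
read_overlay <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] > 3L) img <- img[, , 1:3]
  round(img * 255)
}
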