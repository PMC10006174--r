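#' Arcsinh transform for cytometry counts
#'
#' The standard variance-stabilizing transform for mass-cytometry
#' intensities: `asinh(x / cofactor)`. With the default cofactor of 5 the
#' transform is close to linear below ~5 counts and logarithmic above. It is
#' strictly monotone and maps 0 to 0.
#'
#' @param values numeric vector/matrix/array of raw intensities.
#' @param cofactor positive divisor applied before `asinh` (default 5).
#' @return Transformed values, same shape as the input.
#' @examples
#' arcsinh_transform(c(0, 5, 50))          # 0, log(1 + sqrt(2)), ...
#' @export
arcsinh_transform <- function(values, cofactor = 5) {
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0) {
    stop("cofactor must be a single positive number")
  }
  asinh(values / cofactor)
}

#' Percentile-based maximum-signal threshold
#'
#' Computes the q-th percentile of all pixels in a channel (linear
#' interpolation between order statistics, the type-7 convention) and clips
#' the channel at that value. This mirrors the per-ROI maximum signal
#' threshold used to suppress rare hot pixels before display and analysis.
#' Clipping never raises a pixel and, on integer count data (whose upper
#' tail is tied), applying the operation twice equals applying it once.
#'
#' @param channel numeric matrix/vector of raw intensities for one channel.
#' @param q percentile in (0, 100], default 98.
#' @return list with `threshold` (the percentile) and `clipped` (the channel
#'   with values above the threshold replaced by it).
#' @export
percentile_threshold <- function(channel, q = 98) {
  if (length(channel) == 0L) stop("channel is empty")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 100) {
    stop("q must lie in (0, 100]")
  }
  thr <- as.numeric(quantile(as.numeric(channel), probs = q / 100,
                             type = 7, names = FALSE))
  list(threshold = thr, clipped = pmin(channel, thr))
}

#' Pixel-by-marker table
#'
#' Constructor for the flat representation downstream stages consume: one
#' row per pixel, one column per marker, plus the 0-based (row, col)
#' coordinates that tie each row back to the raster.
#'
#' @param values `N x M` numeric matrix of transformed intensities.
#' @param coords `N x 2` integer matrix of 0-based (row, col) coordinates.
#' @param marker_names length-M character vector.
#' @param image_dim integer `c(H, W)` of the source raster.
#' @param source_roi optional region name the table was extracted from.
#' @return A `pixel_table` object.
#' @export
pixel_table <- function(values, coords, marker_names, image_dim,
                        source_roi = NULL) {
  values <- as.matrix(values)
  coords <- as.matrix(coords)
  if (nrow(values) != nrow(coords)) stop("values and coords disagree on N")
  if (ncol(values) != length(marker_names)) {
    stop("values and marker_names disagree on M")
  }
  if (nrow(coords) && (any(coords < 0) || any(coords[, 1] >= image_dim[1]) ||
                       any(coords[, 2] >= image_dim[2]))) {
    stop("coords fall outside the image bounds")
  }
  colnames(values) <- marker_names
  structure(list(values = values, coords = coords,
                 marker_names = marker_names,
                 image_dim = as.integer(image_dim),
                 source_roi = source_roi),
            class = "pixel_table")
}

#' @export
print.pixel_table <- function(x, ...) {
  cat(sprintf("pixel_table: %d pixels x %d markers (image %d x %d)\n",
              nrow(x$values), ncol(x$values), x$image_dim[1], x$image_dim[2]))
  invisible(x)
}

#' @export
dim.pixel_table <- function(x) dim(x$values)

#' Flatten a channel stack into a pixel table
#'
#' Selects markers, optionally restricts to a pixel mask, percentile-clips
#' each raw channel (maximum-signal threshold) and arcsinh-transforms the
#' result. Rows are emitted in row-major raster order so that `coords`
#' invert the flattening exactly.
#'
#' @param stack a [channel_stack()].
#' @param markers character vector of marker names to keep (default: whole
#'   panel).
#' @param mask optional `H x W` logical matrix selecting pixels.
#' @param cofactor arcsinh cofactor (default 5).
#' @param percentile maximum-signal percentile applied per channel before
#'   the transform (default 98); `NULL` disables clipping.
#' @param source_roi optional region name recorded in the table.
#' @return A [pixel_table()].
#' @export
flatten <- function(stack, markers = NULL, mask = NULL, cofactor = 5,
                    percentile = 98, source_roi = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  panel_names <- stack$panel$marker_name
  if (is.null(markers)) markers <- panel_names
  unknown <- setdiff(markers, panel_names)
  if (length(unknown)) {
    stop("unknown marker name(s): ", paste(unknown, collapse = ", "))
  }
  d <- dim(stack$data)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2])) {
      stop("mask dimensions do not match the image")
    }
  } else {
    mask <- matrix(TRUE, d[1], d[2])
  }
  # row-major order: iterate rows, then columns
  sel <- which(t(mask))                       # t() yields row-major ordering
  wcol <- (sel - 1L) %% d[2]                  # 0-based column
  hrow <- (sel - 1L) %/% d[2]                 # 0-based row
  vals <- matrix(0, length(sel), length(markers))
  for (j in seq_along(markers)) {
    ch <- stack$data[, , markers[j], drop = TRUE]
    if (!is.null(percentile)) ch <- percentile_threshold(ch, percentile)$clipped
    ch <- arcsinh_transform(ch, cofactor)
    vals[, j] <- ch[cbind(hrow + 1L, wcol + 1L)]
  }
  pixel_table(vals, cbind(row = hrow, col = wcol), markers, d[1:2],
              source_roi = source_roi)
}

#' Scatter pixel-table values back onto a raster
#'
#' Inverse of [flatten()] for a single marker column: writes each row's
#' value at its recorded (row, col) coordinate; unselected pixels get
#' `fill`.
#'
#' @param table a [pixel_table()].
#' @param marker marker column to scatter.
#' @param fill value for pixels not present in the table (default `NA`).
#' @return `H x W` numeric matrix.
#' @export
scatter_to_image <- function(table, marker, fill = NA_real_) {
  stopifnot(inherits(table, "pixel_table"))
  if (!marker %in% table$marker_names) stop("unknown marker: ", marker)
  img <- matrix(fill, table$image_dim[1], table$image_dim[2])
  img[cbind(table$coords[, 1] + 1L, table$coords[, 2] + 1L)] <-
    table$values[, marker]
  img
}

# subset rows of a pixel table, keeping coords/metadata consistent
subset_pixel_table <- function(table, idx) {
  pixel_table(table$values[idx, , drop = FALSE],
              table$coords[idx, , drop = FALSE],
              table$marker_names, table$image_dim, table$source_roi)
}
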