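#' Default 9-color class palette
#'
#' Nine maximally distinct qualitative colors plus black background, fixed
#' in the package so figures are reproducible across runs. The renderer
#' displays at most 9 classes with unique colors in one image.
#'
#' @return A `palette` object: list with `colors` (`n x 3` byte matrix,
#'   one row per class) and `background` (length-3 byte vector).
#' @export
default_palette <- function() {
  cols <- c("#E6194B", "#3CB44B", "#FFE119", "#4363D8", "#F58231",
            "#911EB4", "#46F0F0", "#F032E6", "#BCF60C")
  make_palette(cols, background = "#000000")
}

#' Build a class palette from hex colors
#'
#' @param colors character vector (<= 9) of distinct hex colors.
#' @param background hex background color, distinct from all class colors.
#' @return A `palette` object.
#' @export
make_palette <- function(colors, background = "#000000") {
  if (length(colors) > 9L) stop("a palette holds at most 9 class colors")
  rgbm <- t(col2rgb(colors))
  bg <- as.integer(col2rgb(background)[, 1])
  keys <- apply(rgbm, 1, paste, collapse = ",")
  if (anyDuplicated(keys)) stop("palette colors must be pairwise distinct")
  if (paste(bg, collapse = ",") %in% keys) {
    stop("background color must differ from every class color")
  }
  structure(list(colors = rgbm, background = bg), class = "palette")
}

#' Back-project a pixel labeling as a colored overlay
#'
#' Paints each labeled pixel with its class color at its original raster
#' position (1 px = 1 um grid preserved, no resampling); background pixels
#' show either the palette background or, when a base channel is supplied,
#' the channel rendered in grayscale (percentile-clipped then min-max
#' scaled to 0..255).
#'
#' @param labeling a `pixel_labeling`.
#' @param palette a [make_palette()] / [default_palette()] object.
#' @param base optional `H x W` numeric matrix shown under the classes.
#' @param base_percentile percentile clip applied to `base` before scaling
#'   (default 98).
#' @return `H x W x 3` numeric array of bytes in `[0, 255]`.
#' @export
backproject <- function(labeling, palette = default_palette(), base = NULL,
                        base_percentile = 98) {
  stopifnot(inherits(labeling, "pixel_labeling"),
            inherits(palette, "palette"))
  lm <- labeling$label_map
  classes <- sort(unique(lm[lm > 0L]))
  if (length(classes) > nrow(palette$colors)) {
    stop(sprintf(paste0("labeling has %d classes but at most %d can be ",
                        "rendered with unique colors; merge or drop classes"),
                 length(classes), nrow(palette$colors)))
  }
  h <- nrow(lm); w <- ncol(lm)
  out <- array(0, dim = c(h, w, 3))
  if (!is.null(base)) {
    if (!identical(dim(base), dim(lm))) {
      stop("base channel dimensions do not match the label map")
    }
    b <- percentile_threshold(base, base_percentile)$clipped
    rngb <- range(b)
    b <- if (diff(rngb) > 0) (b - rngb[1]) / diff(rngb) * 255 else b * 0
    for (ch in 1:3) out[, , ch] <- b
  } else {
    for (ch in 1:3) out[, , ch] <- palette$background[ch]
  }
  for (i in seq_along(classes)) {
    sel <- lm == classes[i]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- palette$colors[i, ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Recover a label map from an overlay
#'
#' Inverse of [backproject()] without a base channel: maps each pixel color
#' back through the palette. Used to verify the color-class bijection.
#'
#' @param rgb_image `H x W x 3` byte array.
#' @param palette the palette used to render it.
#' @param classes integer labels in render order (defaults to `1..n` for
#'   the colors actually present).
#' @return `H x W` integer label map.
#' @export
unproject <- function(rgb_image, palette, classes = NULL) {
  h <- dim(rgb_image)[1]; w <- dim(rgb_image)[2]
  key <- matrix(paste(rgb_image[, , 1], rgb_image[, , 2], rgb_image[, , 3],
                      sep = ","), h, w)
  color_keys <- apply(palette$colors, 1, paste, collapse = ",")
  lm <- matrix(0L, h, w)
  if (is.null(classes)) classes <- seq_along(color_keys)
  for (i in seq_along(color_keys)) {
    lm[key == color_keys[i]] <- classes[i]
  }
  lm
}
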