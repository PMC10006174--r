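#' Specification for a synthetic multiplexed image
#'
#' Describes a planted tissue layout: rectangular or disc-shaped regions in
#' a raster, per-class marker mean intensities, a rule assigning classes to
#' regions with mixing fractions, and a count-like noise model. Together
#' with the seed this fully determines the generated image, so every
#' downstream stage can be tested against known ground truth.
#'
#' Geometries use 0-based (row, col) pixel coordinates with pixel-center
#' inclusion: pixel (r, c) belongs to a disc iff its center (r, c) lies
#' within the radius, and to a rectangle iff `row_min <= r <= row_max` and
#' `col_min <= c <= col_max`.
#'
#' @param image_height,image_width raster dimensions in pixels.
#' @param regions list of regions, each a list with `name`, `shape`
#'   (`"rect"` or `"disc"`), geometry fields (`row_min`, `row_max`,
#'   `col_min`, `col_max` for rect; `center_row`, `center_col`, `radius`
#'   for disc) and `group` (one of `"LF"`, `"non-LF"`, `"background"`).
#' @param classes named list mapping class name to a named numeric vector
#'   of per-marker mean intensities (non-negative counts).
#' @param class_map named list mapping region name to a named numeric
#'   vector of class mixing fractions in `[0, 1]` summing to 1.
#' @param noise_model `"poisson"` or `"lognormal"`.
#' @param sigma lognormal sigma (ignored for Poisson noise).
#' @param seed integer seed; generation is a pure function of (spec, seed).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(image_height, image_width, regions, classes,
                           class_map, noise_model = c("poisson", "lognormal"),
                           sigma = 0.3, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(image_height >= 1, image_width >= 1)
  region_names <- vapply(regions, function(r) r$name, character(1))
  if (anyDuplicated(region_names)) stop("region names must be unique")
  for (r in regions) {
    if (!r$group %in% c("LF", "non-LF", "background")) {
      stop("region group must be LF, non-LF or background: ", r$name)
    }
    if (r$shape == "rect") {
      if (r$row_min < 0 || r$col_min < 0 || r$row_max >= image_height ||
          r$col_max >= image_width || r$row_min > r$row_max ||
          r$col_min > r$col_max) {
        stop("rectangle out of bounds: ", r$name)
      }
    } else if (r$shape == "disc") {
      if (r$center_row - r$radius < 0 || r$center_col - r$radius < 0 ||
          r$center_row + r$radius >= image_height ||
          r$center_col + r$radius >= image_width) {
        stop("disc out of bounds: ", r$name)
      }
    } else stop("unknown shape: ", r$shape)
  }
  if (!length(classes)) stop("at least one class is required")
  markers <- names(classes[[1]])
  for (cl in names(classes)) {
    v <- classes[[cl]]
    if (!identical(names(v), markers)) {
      stop("all classes must declare the same markers in the same order")
    }
    if (any(v < 0)) stop("mean intensities must be non-negative: ", cl)
  }
  for (rn in names(class_map)) {
    if (!rn %in% region_names) stop("class_map names unknown region: ", rn)
    fr <- class_map[[rn]]
    if (any(fr < 0) || any(fr > 1)) stop("mixing fractions must be in [0,1]")
    if (abs(sum(fr) - 1) > 1e-9) {
      stop("mixing fractions for region ", rn, " must sum to 1")
    }
    if (!all(names(fr) %in% names(classes))) {
      stop("class_map for region ", rn, " names an undeclared class")
    }
  }
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 regions = regions, classes = classes, class_map = class_map,
                 noise_model = noise_model, sigma = sigma,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# rasterize one region geometry to a logical mask (pixel-center inclusion)
rasterize_region <- function(region, h, w) {
  r <- matrix(rep(0:(h - 1L), times = w), h, w)
  cc <- matrix(rep(0:(w - 1L), each = h), h, w)
  if (region$shape == "rect") {
    r >= region$row_min & r <= region$row_max &
      cc >= region$col_min & cc <= region$col_max
  } else {
    (r - region$center_row)^2 + (cc - region$center_col)^2 <=
      region$radius^2
  }
}

# run expr with a private RNG stream; global .Random.seed is untouched
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic multiplexed image with ground truth
#'
#' Paints the declared regions, samples a class per pixel according to the
#' region's mixing fractions, and draws each channel intensity from the
#' noise model around the class mean: Poisson with the mean as rate, or
#' lognormal (mean multiplied by `exp(N(0, sigma^2))`). Pixels outside all
#' regions have zero mean in every channel. The same spec and seed always
#' produce bit-identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `stack` (a [channel_stack()]) and `truth` (list with
#'   `label_map`, an `H x W` integer raster where 0 is background and k >= 1
#'   indexes `names(spec$classes)`, and `roi_set`, the rasterized regions).
#' @export
generate_multiplex_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$image_height; w <- spec$image_width
  markers <- names(spec$classes[[1]])
  class_names <- names(spec$classes)

  masks <- lapply(spec$regions, rasterize_region, h = h, w = w)
  names(masks) <- vapply(spec$regions, function(r) r$name, character(1))

  # overlapping regions are only legal when they agree on the class rule
  if (length(masks) > 1L) {
    for (i in seq_along(masks)[-1L]) for (j in seq_len(i - 1L)) {
      if (any(masks[[i]] & masks[[j]])) {
        rule_i <- spec$class_map[[names(masks)[i]]]
        rule_j <- spec$class_map[[names(masks)[j]]]
        if (!identical(rule_i, rule_j)) {
          stop("regions ", names(masks)[j], " and ", names(masks)[i],
               " overlap with conflicting class assignments")
        }
      }
    }
  }

  label_map <- matrix(0L, h, w)
  with_private_seed(spec$seed, {
    for (rn in names(spec$class_map)) {
      m <- masks[[rn]]
      idx <- which(m)
      if (!length(idx)) next
      fr <- spec$class_map[[rn]]
      ids <- match(names(fr), class_names)
      cls <- ids[sample.int(length(ids), length(idx), replace = TRUE,
                            prob = fr)]
      label_map[idx] <- cls
    }
    mean_stack <- array(0, dim = c(h, w, length(markers)))
    for (k in seq_along(class_names)) {
      sel <- label_map == k
      if (!any(sel)) next
      mu <- spec$classes[[k]]
      for (j in seq_along(markers)) {
        plane <- mean_stack[, , j]
        plane[sel] <- mu[j]
        mean_stack[, , j] <- plane
      }
    }
    data <- array(0, dim = c(h, w, length(markers)))
    n_px <- h * w
    for (j in seq_along(markers)) {
      mu <- as.numeric(mean_stack[, , j])
      x <- if (spec$noise_model == "poisson") {
        as.numeric(rpois(n_px, lambda = mu))
      } else {
        mu * exp(rnorm(n_px, 0, spec$sigma))
      }
      data[, , j] <- matrix(x, h, w)
    }
  })

  panel <- marker_panel(seq_along(markers) - 1L,
                        paste0("M", seq_along(markers)), markers)
  rois <- roi_set(lapply(seq_along(spec$regions), function(i) {
    list(name = spec$regions[[i]]$name, mask = masks[[i]],
         group = spec$regions[[i]]$group)
  }))
  list(stack = channel_stack(data, panel),
       truth = list(label_map = label_map, roi_set = rois,
                    class_names = class_names))
}

#' Generate labelled pixel clusters without spatial structure
#'
#' A lighter fixture for embedding and hierarchy tests: draws `n_per_class`
#' pixel rows around each signature row under the chosen noise model.
#'
#' @param n_per_class pixels per class (scalar or one per class).
#' @param signatures numeric matrix, one row per class, one column per
#'   marker, with dimnames.
#' @param noise_model `"poisson"`, `"lognormal"` or `"gaussian"` (additive
#'   `N(0, sigma)`, truncated at 0).
#' @param sigma noise scale for lognormal/gaussian.
#' @param seed integer seed.
#' @return list with `table` (a [pixel_table()] of raw->arcsinh-free values;
#'   values are emitted untransformed) and `labels` (integer class per row).
#' @export
generate_pixel_clusters <- function(n_per_class, signatures,
                                    noise_model = "gaussian", sigma = 0.5,
                                    seed = 1L) {
  if (is.null(dim(signatures)) || nrow(signatures) < 1L) {
    stop("signatures must be a non-empty class x marker matrix")
  }
  n_class <- nrow(signatures)
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, n_class)
  if (any(n_per_class < 1L)) stop("n_per_class must be >= 1")
  n <- sum(n_per_class)
  m <- ncol(signatures)
  vals <- matrix(0, n, m)
  labels <- integer(n)
  with_private_seed(seed, {
    at <- 0L
    for (k in seq_len(n_class)) {
      rows <- (at + 1L):(at + n_per_class[k])
      mu <- signatures[k, ]
      for (j in seq_len(m)) {
        vals[rows, j] <- switch(noise_model,
          poisson   = as.numeric(rpois(length(rows), mu[j])),
          lognormal = mu[j] * exp(rnorm(length(rows), 0, sigma)),
          gaussian  = pmax(0, mu[j] + rnorm(length(rows), 0, sigma)),
          stop("unknown noise model: ", noise_model))
      }
      labels[rows] <- k
      at <- at + n_per_class[k]
    }
  })
  tab <- pixel_table(vals, cbind(row = 0:(n - 1L), col = rep(0L, n)),
                     colnames(signatures), c(n, 1L))
  list(table = tab, labels = labels)
}

#' Read a synthetic-image spec from a YAML file
#' @param path YAML file mirroring the [synthetic_spec()] fields.
#' @return A [synthetic_spec()].
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  classes <- lapply(y$classes, function(v) unlist(v))
  class_map <- lapply(y$class_map, function(v) unlist(v))
  synthetic_spec(y$image_height, y$image_width, y$regions, classes,
                 class_map, noise_model = y$noise_model,
                 sigma = if (is.null(y$sigma)) 0.3 else y$sigma,
                 seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Built-in synthetic lymphoid-follicle study design
#'
#' The default fixture mirrors the study design at desk scale: a tissue
#' raster containing 7 lymphoid-follicle (LF) discs and 5 equal-area non-LF
#' control boxes, planted cell classes echoing the phenotypes resolvable by
#' pixel analysis (T cell, ILC, B cell, macrophage, myeloid, epithelium,
#' stroma) over a panel of immune and structural markers, with CD161/CD69
#' co-expression enriched inside the LFs.
#'
#' @param image_height,image_width raster size (default 160 x 220).
#' @param noise_model,sigma noise settings (default lognormal, sigma 0.3).
#' @param seed integer seed.
#' @param lf_n,nonlf_n number of LF discs and non-LF boxes (defaults 7
#'   and 5, the quantification design).
#' @return A [synthetic_spec()].
#' @export
lf_study_spec <- function(image_height = 160, image_width = 220,
                          noise_model = "lognormal", sigma = 0.3, seed = 1L,
                          lf_n = 7L, nonlf_n = 5L) {
  markers <- c("CD45", "CD3", "CD7", "CD20", "HLA-DR", "CD163",
               "CD161", "CD69", "E-cadherin", "vimentin")
  sig <- function(...) {
    v <- setNames(rep(0, length(markers)), markers)  # IMC-like zero background
    args <- list(...)
    v[names(args)] <- unlist(args)
    v
  }
  classes <- list(
    `T cell`     = sig(CD45 = 40, CD3 = 35, CD7 = 30, CD161 = 12, CD69 = 12),
    ILC          = sig(CD45 = 40, CD7 = 30, CD161 = 25, CD69 = 25),
    `B cell`     = sig(CD45 = 40, CD20 = 35, `HLA-DR` = 25),
    macrophage   = sig(CD45 = 30, CD163 = 35, `HLA-DR` = 25),
    myeloid      = sig(CD45 = 30, `HLA-DR` = 30),
    epithelium   = sig(`E-cadherin` = 45),
    stroma       = sig(vimentin = 30)
  )
  # 7 LF discs across the raster, 5 equal-area control boxes, a strip of
  # epithelium along the top and stroma filling the rest; geometry is laid
  # out in raster fractions so the design scales with the requested size
  if (image_height < 64 || image_width < 88) {
    stop("the LF study design needs at least a 64 x 88 raster")
  }
  h <- image_height; w <- image_width
  rad <- round(0.0688 * h)
  lf_centers <- list(
    c(round(0.28 * h), round(0.114 * w)), c(round(0.28 * h), round(0.341 * w)),
    c(round(0.28 * h), round(0.568 * w)), c(round(0.28 * h), round(0.795 * w)),
    c(round(0.656 * h), round(0.182 * w)), c(round(0.656 * h), round(0.477 * w)),
    c(round(0.656 * h), round(0.773 * w)))[seq_len(lf_n)]
  regions <- list(
    list(name = "epithelium_band", shape = "rect", row_min = 0,
         row_max = round(0.09 * h), col_min = 0, col_max = w - 1,
         group = "background"),
    list(name = "stroma_field", shape = "rect", row_min = round(0.8125 * h),
         row_max = h - 1, col_min = 0, col_max = w - 1,
         group = "background")
  )
  class_map <- list(
    epithelium_band = c(epithelium = 1),
    stroma_field = c(stroma = 0.7, macrophage = 0.15, myeloid = 0.15)
  )
  for (i in seq_len(lf_n)) {
    nm <- paste0("LF", i)
    ctr <- lf_centers[[i]]
    regions[[length(regions) + 1L]] <-
      list(name = nm, shape = "disc", center_row = ctr[1],
           center_col = ctr[2], radius = rad, group = "LF")
    class_map[[nm]] <- c(`B cell` = 0.4, `T cell` = 0.25, ILC = 0.25,
                         myeloid = 0.1)
  }
  # non-LF boxes: lamina-propria-like areas of similar surface without
  # the LF aggregate (sparse immune pixels, CD161+CD69+ rare)
  side <- round(sqrt(pi) * rad)     # area-matched square
  nonlf_origin <- list(
    c(round(0.4375 * h), round(0.045 * w)),
    c(round(0.4375 * h), round(0.273 * w)),
    c(round(0.4375 * h), round(0.523 * w)),
    c(round(0.4375 * h), round(0.75 * w)),
    c(round(0.1125 * h), round(0.432 * w)))[seq_len(nonlf_n)]
  for (i in seq_len(nonlf_n)) {
    nm <- paste0("nonLF", i)
    o <- nonlf_origin[[i]]
    regions[[length(regions) + 1L]] <-
      list(name = nm, shape = "rect", row_min = o[1],
           row_max = o[1] + side - 1, col_min = o[2],
           col_max = o[2] + side - 1, group = "non-LF")
    class_map[[nm]] <- c(stroma = 0.8, `T cell` = 0.08, macrophage = 0.12)
  }
  synthetic_spec(image_height, image_width, regions, classes, class_map,
                 noise_model = noise_model, sigma = sigma, seed = seed)
}
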