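#' Default double-positive thresholds for raw channels
#'
#' The per-channel positivity threshold for pixel calls: the channel's
#' maximum-signal percentile (98th by default, over all pixels in the ROI
#' image) scaled by the positivity quantile. Declared as a configurable
#' convention.
#'
#' @param stack a [channel_stack()].
#' @param markers marker names to compute thresholds for.
#' @param percentile maximum-signal percentile (default 98).
#' @param positivity_quantile scale factor in (0, 1] (default 0.6).
#' @return named numeric vector of thresholds on the raw count scale.
#' @export
default_dp_thresholds <- function(stack, markers, percentile = 98,
                                  positivity_quantile = 0.6) {
  vapply(markers, function(m) {
    positivity_quantile *
      percentile_threshold(get_channel(stack, m), percentile)$threshold
  }, numeric(1))
}

#' Count double-positive pixels inside a region
#'
#' A pixel is double-positive when its intensity is at or above the
#' threshold in both marker channels (boundary inclusive). Counts and the
#' fraction are computed over the region mask only.
#'
#' @param stack a [channel_stack()].
#' @param marker_a,marker_b marker names (e.g. `"CD161"`, `"CD69"`).
#' @param roi one region: list with `name`, `mask` (`H x W` logical),
#'   `group`.
#' @param thresholds named numeric vector holding thresholds for both
#'   markers (raw count scale); defaults to [default_dp_thresholds()].
#' @return A one-row data.frame: `region`, `group`, `positive_count`,
#'   `total_count`, `fraction`.
#' @export
count_double_positive <- function(stack, marker_a, marker_b, roi,
                                  thresholds = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  for (m in c(marker_a, marker_b)) {
    if (!m %in% stack$panel$marker_name) stop("marker not in panel: ", m)
  }
  if (!any(roi$mask)) stop("empty ROI: ", roi$name)
  if (is.null(thresholds)) {
    thresholds <- default_dp_thresholds(stack, c(marker_a, marker_b))
  }
  if (!all(c(marker_a, marker_b) %in% names(thresholds))) {
    stop("thresholds must be named for both markers")
  }
  a <- get_channel(stack, marker_a)
  b <- get_channel(stack, marker_b)
  pos <- a >= thresholds[[marker_a]] & b >= thresholds[[marker_b]]
  total <- sum(roi$mask)
  cnt <- sum(pos & roi$mask)
  data.frame(region = roi$name, group = roi$group,
             positive_count = cnt, total_count = total,
             fraction = cnt / total, stringsAsFactors = FALSE)
}

#' Quantify double-positive pixels across an ROI set
#'
#' @inheritParams count_double_positive
#' @param rois a [roi_set()].
#' @return data.frame with one row per region (see
#'   [count_double_positive()]).
#' @export
quantify_rois <- function(stack, marker_a, marker_b, rois,
                          thresholds = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  if (!length(rois$regions)) stop("ROI set is empty")
  if (is.null(thresholds)) {
    thresholds <- default_dp_thresholds(stack, c(marker_a, marker_b))
  }
  do.call(rbind, lapply(rois$regions, function(r) {
    count_double_positive(stack, marker_a, marker_b, r, thresholds)
  }))
}

# cache of exact null U distributions, keyed by "n1,n2"
.mw_cache <- new.env(parent = emptyenv())

mw_null_u <- function(n1, n2) {
  key <- paste0(n1, ",", n2)
  if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
  n <- n1 + n2
  choices <- combn(n, n1)
  u_all <- colSums(matrix(seq_len(n)[choices], nrow = n1)) -
    n1 * (n1 + 1) / 2
  .mw_cache[[key]] <- u_all
  u_all
}

#' One-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two groups of per-region fractions. U is computed
#' from mid-ranks. When the combined sample size is at most 20 and there
#' are no ties, the one-tailed p-value is exact: every arrangement of group
#' labels over the pooled ranks is enumerated. Otherwise the normal
#' approximation with tie correction and continuity correction is used; on
#' that path a U exactly at its null mean (e.g. two identical constant
#' groups, where complete tying degenerates the variance) returns p = 0.5
#' by symmetry convention.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param direction `"greater"` tests the hypothesis that `group_a` tends
#'   larger than `group_b`; `"less"` the reverse.
#' @param exact_max largest combined size for which enumeration is used
#'   (default 20).
#' @return An `mw_test` object: list with `U` (for `group_a`),
#'   `p_one_tailed`, `method` (`"exact"` or `"normal-approximation"`),
#'   `n1`, `n2`, `direction`.
#' @examples
#' mann_whitney_one_tailed(c(5, 6, 7), c(1, 2, 3), "greater")
#' @export
mann_whitney_one_tailed <- function(group_a, group_b,
                                    direction = c("greater", "less"),
                                    exact_max = 20L) {
  direction <- match.arg(direction)
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)                           # mid-ranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  has_ties <- anyDuplicated(pooled) > 0L
  n <- n1 + n2
  if (!has_ties && n <= exact_max) {
    # exact: U for every C(n, n1) placement of group-a labels over ranks;
    # without ties the ranks are 1..n, so the null U distribution depends
    # only on (n1, n2) and is cached across calls
    u_all <- mw_null_u(n1, n2)
    p <- if (direction == "greater") mean(u_all >= U) else mean(u_all <= U)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (U == mu || sigma2 <= 0) {
      p <- 0.5
    } else {
      cc <- 0.5                                # continuity correction
      z <- if (direction == "greater") (U - mu - cc) / sqrt(sigma2)
           else (U - mu + cc) / sqrt(sigma2)
      p <- if (direction == "greater") pnorm(z, lower.tail = FALSE)
           else pnorm(z)
    }
    method <- "normal-approximation"
  }
  structure(list(U = U, p_one_tailed = p, method = method,
                 n1 = n1, n2 = n2, direction = direction),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.4g (n1 = %d, n2 = %d), one-tailed p = %.4g [%s, %s]\n",
              x$U, x$n1, x$n2, x$p_one_tailed, x$method, x$direction))
  invisible(x)
}

#' Compare double-positive fractions between two region groups
#'
#' Runs [quantify_rois()] and applies the one-tailed Mann-Whitney test to
#' the per-region fractions of `group_a` versus `group_b` regions
#' (fractions normalize for region area; raw counts are retained in the
#' table).
#'
#' @inheritParams quantify_rois
#' @param group_a,group_b group tags (defaults `"LF"` and `"non-LF"`).
#' @param direction hypothesis direction for `group_a` (default
#'   `"greater"`).
#' @return list with `table` (the per-region data.frame) and `test`
#'   (an `mw_test`).
#' @export
compare_groups <- function(stack, marker_a, marker_b, rois,
                           thresholds = NULL, group_a = "LF",
                           group_b = "non-LF", direction = "greater") {
  tab <- quantify_rois(stack, marker_a, marker_b, rois, thresholds)
  fa <- tab$fraction[tab$group == group_a]
  fb <- tab$fraction[tab$group == group_b]
  if (!length(fa) || !length(fb)) {
    stop(sprintf("groups '%s' and '%s' must both be present", group_a,
                 group_b))
  }
  list(table = tab,
       test = mann_whitney_one_tailed(fa, fb, direction = direction))
}

#' Write a quantification table with the test as commented footer
#'
#' @param result a [compare_groups()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_quantification <- function(result, path) {
  write.table(result$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  t <- result$test
  footer <- c(
    sprintf("# mann_whitney_one_tailed U=%.6g method=%s direction=%s", t$U,
            t$method, t$direction),
    sprintf("# n1=%d n2=%d p_one_tailed=%.8g", t$n1, t$n2, t$p_one_tailed))
  con <- file(path, open = "a")
  writeLines(footer, con)
  close(con)
  invisible(path)
}
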