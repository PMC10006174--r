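# shared fixtures: small, fully synthetic, built at test time

# two well-separated marker signatures (mean separation >= 10x noise sd)
two_blob_signatures <- function() {
  matrix(c(10, 0, 0,
           0, 10, 10),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("A", "B"), c("m1", "m2", "m3")))
}

two_blob_fixture <- function(n = 60, sigma = 0.5, seed = 42) {
  generate_pixel_clusters(n, two_blob_signatures(),
                          noise_model = "gaussian", sigma = sigma,
                          seed = seed)
}

# a small 4-class image spec with distinct signatures (used by the
# planted-structure recovery checks)
four_class_spec <- function(seed = 1, sigma = 0.3, h = 60, w = 60) {
  markers <- c("CD45", "CD3", "CD20", "CD163", "E-cadherin")
  classes <- list(
    Tcell  = c(CD45 = 40, CD3 = 35, CD20 = 1, CD163 = 1, `E-cadherin` = 1),
    Bcell  = c(CD45 = 40, CD3 = 1, CD20 = 35, CD163 = 1, `E-cadherin` = 1),
    mac    = c(CD45 = 30, CD3 = 1, CD20 = 1, CD163 = 35, `E-cadherin` = 1),
    epi    = c(CD45 = 1, CD3 = 1, CD20 = 1, CD163 = 1, `E-cadherin` = 45))
  names(classes[[1]]) <- markers   # guard against name normalization
  regions <- list(
    list(name = "q1", shape = "rect", row_min = 0, row_max = h / 2 - 1,
         col_min = 0, col_max = w / 2 - 1, group = "non-LF"),
    list(name = "q2", shape = "rect", row_min = 0, row_max = h / 2 - 1,
         col_min = w / 2, col_max = w - 1, group = "non-LF"),
    list(name = "q3", shape = "rect", row_min = h / 2, row_max = h - 1,
         col_min = 0, col_max = w / 2 - 1, group = "LF"),
    list(name = "q4", shape = "rect", row_min = h / 2, row_max = h - 1,
         col_min = w / 2, col_max = w - 1, group = "LF"))
  class_map <- list(q1 = c(Tcell = 1), q2 = c(Bcell = 1),
                    q3 = c(mac = 1), q4 = c(epi = 1))
  synthetic_spec(h, w, regions, classes, class_map,
                 noise_model = "lognormal", sigma = sigma, seed = seed)
}

# run the full chain on a 4-class image; returns truth and prediction
run_recovery_chain <- function(seed, sigma = 0.3) {
  spec <- four_class_spec(seed = seed, sigma = sigma)
  gen <- generate_multiplex_image(spec)
  tab <- flatten(gen$stack)
  g <- build_knn_graph(tab, k = 15)
  h <- build_hierarchy(g, n_scales = 2, seed = seed + 1)
  e <- embed_scale(h, 1, params = list(iterations = 500), seed = seed + 2)
  cl <- cluster_embedding(e)
  lab <- expand_to_pixels(h, 1, cl)
  list(truth = gen$truth, pred = lab, hierarchy = h, table = tab,
       clusters = cl, stack = gen$stack)
}
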