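test_that("noise-free generation paints exact class means everywhere", {
  classes <- list(only = c(mA = 12, mB = 12))
  regions <- list(list(name = "all", shape = "rect", row_min = 0,
                       row_max = 9, col_min = 0, col_max = 9,
                       group = "background"))
  spec <- synthetic_spec(10, 10, regions, classes,
                         list(all = c(only = 1)),
                         noise_model = "lognormal", sigma = 0, seed = 7)
  gen <- generate_multiplex_image(spec)
  expect_true(all(gen$stack$data == 12))
  expect_true(all(gen$truth$label_map == 1L))
})

test_that("identical spec and seed give bit-identical images", {
  spec <- four_class_spec(seed = 7)
  g1 <- generate_multiplex_image(spec)
  g2 <- generate_multiplex_image(spec)
  expect_identical(g1$stack$data, g2$stack$data)
  expect_identical(g1$truth$label_map, g2$truth$label_map)
  # and serialization round-trips byte-for-byte
  f1 <- tempfile(fileext = ".tiff"); f2 <- tempfile(fileext = ".tiff")
  write_multichannel_tiff(g1$stack, f1)
  write_multichannel_tiff(g2$stack, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("disc rasterization matches brute-force point-in-disc testing", {
  classes <- list(A = c(m = 20))
  regions <- list(list(name = "disc", shape = "disc", center_row = 50,
                       center_col = 50, radius = 10, group = "LF"))
  spec <- synthetic_spec(100, 100, regions, classes,
                         list(disc = c(A = 1)), noise_model = "poisson",
                         seed = 1)
  gen <- generate_multiplex_image(spec)
  # oracle: test every pixel center against the disc equation
  inside <- 0L
  for (r in 0:99) for (cc in 0:99) {
    if ((r - 50)^2 + (cc - 50)^2 <= 100) inside <- inside + 1L
  }
  expect_identical(sum(gen$truth$label_map == 1L), inside)
})

test_that("foreground pixel count equals the sum of rasterized region areas", {
  spec <- four_class_spec(seed = 3)
  gen <- generate_multiplex_image(spec)
  area <- sum(vapply(gen$truth$roi_set$regions,
                     function(r) sum(r$mask), integer(1)))
  expect_identical(sum(gen$truth$label_map > 0L), area)
})

test_that("overlapping regions with conflicting classes are rejected by name", {
  classes <- list(A = c(m = 5), B = c(m = 9))
  regions <- list(
    list(name = "left", shape = "rect", row_min = 0, row_max = 9,
         col_min = 0, col_max = 6, group = "LF"),
    list(name = "right", shape = "rect", row_min = 0, row_max = 9,
         col_min = 4, col_max = 9, group = "LF"))
  spec <- synthetic_spec(10, 10, regions, classes,
                         list(left = c(A = 1), right = c(B = 1)),
                         noise_model = "poisson", seed = 1)
  expect_error(generate_multiplex_image(spec), "left.*right|right.*left")
})

test_that("pixel-cluster fixture has the declared shape and labels", {
  sig <- two_blob_signatures()
  out <- generate_pixel_clusters(10, sig, seed = 5)
  expect_equal(nrow(out$table$values), 20)
  expect_equal(as.vector(table(out$labels)), c(10, 10))
  # zero noise: rows replicate the signature exactly
  out0 <- generate_pixel_clusters(4, sig[1, , drop = FALSE],
                                  noise_model = "gaussian", sigma = 0,
                                  seed = 5)
  expect_true(all(t(out0$table$values) == sig[1, ]))
  expect_error(generate_pixel_clusters(5, sig[0, , drop = FALSE]),
               "non-empty")
})

test_that("well-separated clusters are recovered by nearest centroid", {
  sig <- two_blob_signatures()   # separation 10 vs sd 0.5 => >= 10x
  out <- two_blob_fixture(n = 50, sigma = 0.5, seed = 11)
  d <- as.matrix(dist(rbind(sig, out$table$values)))[-(1:2), 1:2]
  pred <- apply(d, 1, which.min)
  expect_identical(as.integer(pred), out$labels)
})

test_that("lognormal class means converge to declared means", {
  mu <- 30; sigma <- 0.2; n <- 2e4
  out <- generate_pixel_clusters(n, matrix(mu, 1, 1,
                                           dimnames = list("a", "m")),
                                 noise_model = "lognormal", sigma = sigma,
                                 seed = 9)
  x <- out$table$values[, 1]
  # lognormal multiplier has mean exp(sigma^2/2)
  expected <- mu * exp(sigma^2 / 2)
  se <- sd(x) / sqrt(n)
  expect_lt(abs(mean(x) - expected), 3 * se)
})

test_that("synthetic spec validates geometry, fractions and means", {
  classes <- list(A = c(m = 5))
  expect_error(synthetic_spec(10, 10, list(
    list(name = "oob", shape = "rect", row_min = 0, row_max = 12,
         col_min = 0, col_max = 5, group = "LF")), classes,
    list(oob = c(A = 1))), "out of bounds")
  regions <- list(list(name = "r", shape = "rect", row_min = 0,
                       row_max = 5, col_min = 0, col_max = 5,
                       group = "LF"))
  expect_error(synthetic_spec(10, 10, regions, classes,
                              list(r = c(A = 0.7))), "sum to 1")
  expect_error(synthetic_spec(10, 10, regions, list(A = c(m = -2)),
                              list(r = c(A = 1))), "non-negative")
})

test_that("spec YAML round-trips through read_synthetic_spec", {
  spec <- four_class_spec(seed = 2)
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    image_height = spec$image_height, image_width = spec$image_width,
    regions = spec$regions,
    classes = lapply(spec$classes, as.list),
    class_map = lapply(spec$class_map, as.list),
    noise_model = spec$noise_model, sigma = spec$sigma, seed = spec$seed),
    f)
  spec2 <- read_synthetic_spec(f)
  expect_identical(generate_multiplex_image(spec)$stack$data,
                   generate_multiplex_image(spec2)$stack$data)
})
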