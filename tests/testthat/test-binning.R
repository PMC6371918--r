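px_of <- function(mat, space = "rgb") chromadist:::pixel_set(as.matrix(mat), space)

test_that("a single-color image fills exactly one histogram bin", {
  px <- px_of(solid_block(c(1, 0, 0), 40))
  h <- histogram_bin(px, bins = c(2, 2, 2))
  expect_length(h$sizes, 8)
  expect_equal(sum(h$sizes), 1)

  filled <- which(h$sizes > 0)
  expect_length(filled, 1)
  expect_equal(unname(h$centers[filled, ]), c(1, 0, 0))
  expect_equal(h$sizes[filled], 1)
  # empty bins sit at their boxes' geometric midpoints
  empties <- setdiff(seq_len(8), filled)
  expect_true(all(h$centers[empties, ] %in% c(0.25, 0.75)))
})

test_that("two well-separated colors land in two bins with exact proportions", {
  px <- px_of(rbind(solid_block(c(0, 1, 1), 30), solid_block(c(1, 0, 0), 30)))
  h <- histogram_bin(px, bins = c(3, 3, 3))
  expect_length(h$sizes, 27)
  nz <- which(h$sizes > 0)
  expect_length(nz, 2)
  expect_equal(unname(h$sizes[nz]), c(0.5, 0.5))
  # red (hi,lo,lo) has the lower linear index than cyan (lo,hi,hi) because the
  # first channel varies fastest
  expect_equal(unname(h$centers[nz[1], ]), c(1, 0, 0))
  expect_equal(unname(h$centers[nz[2], ]), c(0, 1, 1))
})

test_that("bins partition half-open intervals with the top bin closed", {
  # 2 bins on [0,1]: 0.5 belongs to the upper bin; 1.0 stays in the top bin
  px <- px_of(rbind(c(0.5, 0, 0), c(1, 0, 0), c(0.49999, 0, 0)))
  h <- histogram_bin(px, bins = c(2, 1, 1))
  expect_equal(h$counts, c(1, 2))
})

test_that("bins are emitted with the first channel index varying fastest", {
  # one pixel in (hi, lo, lo) must land at linear index 2 for 2x2x2 bins
  px <- px_of(matrix(c(0.9, 0.1, 0.1), 1))
  h <- histogram_bin(px, bins = c(2, 2, 2))
  expect_equal(which(h$sizes > 0), 2L)
  # and (lo, hi, lo) at index 3
  px2 <- px_of(matrix(c(0.1, 0.9, 0.1), 1))
  expect_equal(which(histogram_bin(px2, bins = c(2, 2, 2))$sizes > 0), 3L)
})

test_that("pixels outside channel bounds raise a named error, not a clamp", {
  px <- px_of(matrix(c(50, 60, 10), 1), space = "lab")
  expect_error(
    histogram_bin(px, bins = c(2, 2, 2),
                  channel_bounds = list(c(0, 100), c(-20, 40), c(0, 50))),
    "a spans")
})

test_that("histogram centers are convex combinations of member pixels", {
  set.seed(21)
  px <- px_of(matrix(runif(900), 300, 3))
  h <- histogram_bin(px, bins = c(3, 3, 3))
  expect_equal(sum(h$sizes), 1, tolerance = 1e-12)
  for (b in which(h$counts > 0)) {
    expect_true(all(h$centers[b, ] >= h$bin_lower[b, ] - 1e-12))
    expect_true(all(h$centers[b, ] <= h$bin_upper[b, ] + 1e-12))
  }
  # refining the grid never changes the total pixel count accounted for
  h2 <- histogram_bin(px, bins = c(6, 6, 6))
  expect_equal(sum(h2$counts), sum(h$counts))
})

test_that("Lab histograms default to L 0-100, a/b -128-127", {
  lab_px <- rgb_to_lab(px_of(rbind(c(1, 0, 0), c(0, 0, 1), c(1, 1, 0))), "D65")
  h <- histogram_bin(lab_px, bins = c(2, 2, 2))
  expect_equal(h$bin_lower[1, ], c(0, -128, -128))
  expect_equal(h$bin_upper[8, ], c(100, 127, 127))
})

test_that("k-means recovers planted, well-separated clusters exactly", {
  colors <- rbind(c(0.05, 0.05, 0.05), c(0.95, 0.05, 0.05), c(0.05, 0.95, 0.95))
  px <- px_of(rbind(solid_block(colors[1, ], 50), solid_block(colors[2, ], 30),
                    solid_block(colors[3, ], 20)))
  km <- kmeans_bin(px, k = 3, seed = 4)
  ord <- order(km$sizes, decreasing = TRUE)
  expect_equal(unname(km$sizes[ord]), c(0.5, 0.3, 0.2))
  expect_equal(unname(km$centers[ord, ]), unname(colors), tolerance = 1e-12)

  # exhaustive check: every pixel is nearer its own center than any other
  d2 <- chromadist:::sqdist_to_centers(px$coords, km$centers)
  expect_true(all(max.col(-d2) == apply(d2, 1, which.min)))

  # independent cross-check of the objective against stats::kmeans
  ref <- stats::kmeans(px$coords, centers = 3, nstart = 10)
  expect_equal(sum(chromadist:::lloyd_kmeans(px$coords, km$centers)$wcss),
               ref$tot.withinss, tolerance = 1e-9)
})

test_that("k-means is deterministic for a fixed seed and degenerate at k = 1", {
  set.seed(31)
  px <- px_of(matrix(runif(600), 200, 3))
  a <- kmeans_bin(px, k = 4, seed = 99)
  b <- kmeans_bin(px, k = 4, seed = 99)
  expect_identical(a$centers, b$centers)
  expect_identical(a$sizes, b$sizes)

  k1 <- kmeans_bin(px, k = 1)
  expect_equal(unname(k1$centers[1, ]), unname(colMeans(px$coords)))
  expect_equal(k1$sizes, 1)

  expect_error(kmeans_bin(px_of(solid_block(c(1, 0, 0), 10)), k = 3),
               "smaller k")
})

test_that("an image set is binned with one spec, sorted, and labeled by stem", {
  d <- tempfile("set")
  generate_quantity_set(d, size = 20)
  sets <- bin_image_set(d, method = "hist", color_space = "rgb",
                        background = NULL, bins = c(3, 3, 3))
  expect_named(sets, c("A", "B", "C", "D", "E"))
  expect_true(all(vapply(sets, function(s) length(s$sizes), integer(1)) == 27))

  # duplicate files give bin-for-bin identical profiles
  d2 <- tempfile("dup"); dir.create(d2)
  file.copy(file.path(d, "C.png"), file.path(d2, "c1.png"))
  file.copy(file.path(d, "C.png"), file.path(d2, "c2.png"))
  two <- bin_image_set(d2, background = NULL)
  expect_equal(two[[1]]$centers, two[[2]]$centers)
  expect_equal(two[[1]]$sizes, two[[2]]$sizes)

  empty_dir <- tempfile("empty"); dir.create(empty_dir)
  expect_error(bin_image_set(empty_dir), "no PNG or JPEG")

  # one broken file: all are attempted, the failure names the file
  bad <- file.path(d2, "bad.png"); writeLines("nope", bad)
  expect_error(bin_image_set(d2, background = NULL), "bad\\.png")
})

test_that("cluster CSVs round trip bit-exact", {
  set.seed(41)
  px <- px_of(matrix(runif(300), 100, 3))
  for (cl in list(histogram_bin(px, c(2, 3, 2), label = "x"),
                  kmeans_bin(px, 3, seed = 2, label = "x"))) {
    path <- tempfile(fileext = ".csv")
    write_clusters(cl, path)
    back <- read_clusters(path)
    expect_identical(back$centers, cl$centers)
    expect_identical(back$sizes, cl$sizes)
    expect_identical(back$counts, cl$counts)
    expect_identical(back$space, cl$space)
    expect_identical(back$method, cl$method)
    if (!is.null(cl$bin_lower)) {
      expect_identical(back$bin_lower, cl$bin_lower)
      expect_identical(back$bin_upper, cl$bin_upper)
    }
  }
})
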