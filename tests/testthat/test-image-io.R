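test_that("background masking keeps exactly the out-of-range pixels", {
  green <- c(0, 1, 0); red <- c(1, 0, 0)
  img <- make_img(rbind(solid_block(green, 50), solid_block(red, 50)), 10, 10)
  bg <- background_range(c(0, 0.6, 0), c(0.4, 1, 0.4))

  px <- mask_background(img, bg)
  expect_equal(nrow(px$coords), 50)
  expect_true(all(px$coords[, 1] == 1 & px$coords[, 2] == 0 & px$coords[, 3] == 0))

  # a range matched by nothing keeps every pixel
  px_all <- mask_background(img, background_range(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(nrow(px_all$coords), 100)

  # flower-bounds semantics: inside on all three channels -> masked
  one <- make_img(matrix(c(0.2, 0.8, 0.1), 1), 1, 1)
  expect_equal(nrow(mask_background(one, bg)$coords), 0)
  # boundary values are inclusive
  exact <- make_img(matrix(c(0, 0.6, 0), 1), 1, 1)
  expect_equal(nrow(mask_background(exact, bg)$coords), 0)
  # conjunction: one channel outside the range -> kept
  off <- make_img(matrix(c(0.5, 0.8, 0.1), 1), 1, 1)
  expect_equal(nrow(mask_background(off, bg)$coords), 1)

  # enumerate a 2x2 image against the range
  four <- make_img(rbind(c(0, 1, 0), c(0, 1, 0), c(1, 0, 0), c(0, 0, 1)), 2, 2)
  expect_equal(nrow(mask_background(four, bg)$coords), 2)
})

test_that("masking conserves pixels, is idempotent, and respects scan order", {
  set.seed(7)
  for (rep in 1:20) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    img <- make_img(matrix(runif(h * w * 3), h * w, 3), h, w)
    lo <- runif(3, 0, 0.5); hi <- lo + runif(3, 0, 0.5)
    bg <- background_range(lo, hi)
    kept <- mask_background(img, bg)
    inside <- sum(apply(matrix(aperm(img, c(3, 2, 1)), nrow = 3), 2, function(p) {
      all(p >= lo & p <= hi)
    }))
    expect_equal(nrow(kept$coords) + inside, h * w)
    # masking the survivors again removes nothing
    survivors <- make_img(kept$coords, nrow(kept$coords), 1)
    expect_equal(nrow(mask_background(survivors, bg)$coords), nrow(kept$coords))
  }

  # row-major scan order: row 1 left-to-right first
  img <- make_img(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)), 2, 2)
  px <- mask_background(img, NULL)
  expect_equal(px$coords[1, ], c(R = 1, G = 0, B = 0))
  expect_equal(px$coords[2, ], c(R = 0, G = 1, B = 0))
  expect_equal(px$coords[3, ], c(R = 0, G = 0, B = 1))
})

test_that("PNG round trip is exact at 8-bit quantization", {
  set.seed(11)
  colors <- round(matrix(runif(48), 16, 3) * 255) / 255
  path <- write_tmp_png(colors, 4, 4)
  loaded <- load_image(path, background = NULL)
  expect_equal(loaded$pixels$coords, colors, ignore_attr = TRUE)
})

test_that("load_image rejects bad inputs and empty objects", {
  expect_error(load_image(tempfile(fileext = ".png")), "not found")

  gray <- tempfile(fileext = ".png")
  png::writePNG(matrix(runif(16), 4, 4), gray)
  expect_error(load_image(gray), "not 3-channel")

  solid_green <- write_tmp_png(solid_block(c(0, 1, 0), 16), 4, 4)
  expect_error(
    load_image(solid_green, background_range(c(0, 0.6, 0), c(0.4, 1, 0.4))),
    "empty object")

  txt <- tempfile(fileext = ".png")
  writeLines("not a png", txt)
  expect_error(load_image(txt), "cannot read image")
})

test_that("fully transparent pixels are background; partial alpha composites over white", {
  img <- array(0, dim = c(1, 3, 4))
  img[1, 1, ] <- c(1, 0, 0, 1)    # opaque red
  img[1, 2, ] <- c(0, 0, 1, 0)    # fully transparent blue -> dropped
  img[1, 3, ] <- c(0, 0, 0, 0.5)  # half-transparent black -> mid-gray
  path <- tempfile(fileext = ".png")
  png::writePNG(img, path)

  px <- load_image(path, background = NULL)$pixels
  expect_equal(nrow(px$coords), 2)
  expect_equal(unname(px$coords[1, ]), c(1, 0, 0))
  expect_equal(unname(px$coords[2, ]), rep(0.5, 3), tolerance = 1 / 255)
})

test_that("multiple background ranges mask their union", {
  img <- make_img(rbind(c(0, 1, 0), c(1, 1, 1), c(1, 0, 0)), 1, 3)
  ranges <- list(background_range(c(0, 0.9, 0), c(0.1, 1, 0.1)),
                 background_range(c(0.9, 0.9, 0.9), c(1, 1, 1)))
  px <- mask_background(img, ranges)
  expect_equal(nrow(px$coords), 1)
  expect_equal(unname(px$coords[1, ]), c(1, 0, 0))
})

test_that("background_range validates its bounds", {
  expect_error(background_range(c(0.5, 0, 0), c(0.4, 1, 1)), "lower bound")
  expect_error(background_range(c(0, 0), c(1, 1)), "triplets")
  expect_error(background_range(c(-0.1, 0, 0), c(1, 1, 1)), "\\[0, 1\\]")
})

test_that("pixel sets export to headered CSV with channel-name columns", {
  px <- chromadist:::pixel_set(matrix(c(0.25, 0.5, 0.75), 1, 3), "lab")
  path <- tempfile(fileext = ".csv")
  write_pixels(px, path)
  back <- read.csv(path)
  expect_equal(names(back), c("L", "a", "b"))
  expect_equal(unlist(back[1, ], use.names = FALSE), c(0.25, 0.5, 0.75))
})
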