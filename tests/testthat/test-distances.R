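test_that("transport plans satisfy their marginals and known optima", {
  plan <- solve_transport(c(1, 0), c(0, 1), matrix(c(0, 5, 5, 0), 2))
  expect_equal(plan$cost, 5)
  expect_equal(rowSums(plan$flows), c(1, 0))
  expect_equal(colSums(plan$flows), c(0, 1))

  set.seed(61)
  for (rep in 1:25) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    s <- runif(m); s <- s / sum(s)
    d <- runif(n); d <- d / sum(d)
    cost <- matrix(runif(m * n, 0, 2), m, n)
    plan <- solve_transport(s, d, cost)
    expect_lt(max(abs(rowSums(plan$flows) - s)), 1e-8)
    expect_lt(max(abs(colSums(plan$flows) - d)), 1e-8)
    expect_true(all(plan$flows >= 0))
    expect_equal(sum(plan$flows), 1, tolerance = 1e-8)
  }

  expect_error(solve_transport(c(1), c(2), matrix(0, 1, 1)), "unbalanced")
  expect_error(solve_transport(c(1), c(1), matrix(-1, 1, 1)), "nonnegative")
})

test_that("EMD between point masses is the center distance; identity is zero", {
  a <- point_mass(c(0, 1, 1))
  b <- point_mass(c(1, 0, 0))
  expect_equal(emd(a, b), sqrt(3), tolerance = 1e-12)
  expect_equal(emd(a, a), 0)
  expect_error(emd(a, rand_clusters(2, "lab")), "different color spaces")
})

test_that("EMD matches the closed-form 1D transport cost on collinear profiles", {
  set.seed(62)
  diag3 <- c(1, 1, 1) / sqrt(3)
  for (rep in 1:40) {
    ka <- sample(2:5, 1); kb <- sample(2:5, 1)
    ta <- runif(ka); tb <- runif(kb)
    wa <- runif(ka); wa <- wa / sum(wa)
    wb <- runif(kb); wb <- wb / sum(wb)
    a <- chromadist:::color_clusters(outer(ta, diag3), wa, wa * 1000, "rgb",
                                     "kmeans", n_source_pixels = 1000)
    b <- chromadist:::color_clusters(outer(tb, diag3), wb, wb * 1000, "rgb",
                                     "kmeans", n_source_pixels = 1000)
    expect_equal(emd(a, b), emd_1d_oracle(ta, wa, tb, wb), tolerance = 1e-9)
  }
})

test_that("EMD scales with the space while chi-squared ignores centers", {
  set.seed(63)
  a <- rand_clusters(4); b <- rand_clusters(4)
  base_emd <- emd(a, b)
  base_col <- color_distance(a, b)
  for (c_scale in c(0.5, 3)) {
    a2 <- a; a2$centers <- a$centers * c_scale
    b2 <- b; b2$centers <- b$centers * c_scale
    expect_equal(emd(a2, b2), c_scale * base_emd, tolerance = 1e-9)
    expect_equal(color_distance(a2, b2), c_scale * base_col, tolerance = 1e-12)
    expect_equal(chi_squared_distance(a2, b2), chi_squared_distance(a, b))
  }
})

test_that("zero-size bins are invisible to EMD but positional for chi-squared", {
  a <- chromadist:::color_clusters(rbind(c(0, 0, 0), c(1, 1, 1)), c(1, 0),
                                   c(10, 0), "rgb", "hist", n_source_pixels = 10)
  b <- chromadist:::color_clusters(rbind(c(0, 0, 0), c(1, 1, 1)), c(0, 1),
                                   c(0, 10), "rgb", "hist", n_source_pixels = 10)
  expect_equal(emd(a, b), sqrt(3))
  expect_equal(chi_squared_distance(a, b), 2)
  expect_equal(chi_squared_distance(a, a), 0)
})

test_that("chi-squared sees only sizes: same proportions, different colors -> 0", {
  black_gray <- two_point(c(0, 0, 0), c(0.5, 0.5, 0.5), t = 0.5)
  black_white <- two_point(c(0, 0, 0), c(1, 1, 1), t = 0.5)
  expect_equal(chi_squared_distance(black_gray, black_white), 0)
  expect_gt(emd(black_gray, black_white), 0)
})

test_that("center-only and weighted metrics evaluate as documented", {
  a <- chromadist:::color_clusters(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 0),
                                   c(10, 0), "rgb", "kmeans", n_source_pixels = 10)
  b <- chromadist:::color_clusters(rbind(c(0.3, 0, 0), c(0, 0.5, 0)), c(0, 1),
                                   c(0, 10), "rgb", "kmeans", n_source_pixels = 10)
  expect_equal(color_distance(a, b), 0.4)  # mean of 0.3 and 0.5
  expect_equal(color_distance(point_mass(c(0, 0, 0)), point_mass(c(1, 1, 1))),
               sqrt(3))

  expect_equal(weighted_pair_distance(a, b, size_weight = 0, color_weight = 1),
               color_distance(a, b))
  expect_equal(weighted_pair_distance(a, b, size_weight = 1, color_weight = 0),
               1)  # mean |size difference| over (1,0) vs (0,1)
  expect_equal(weighted_pair_distance(a, a, 0.3, 0.7), 0)
  expect_error(weighted_pair_distance(a, b, 0.5, 0.7), "sum to 1")
})

test_that("distance matrices are symmetric, zero-diagonal, and validated", {
  set.seed(64)
  sets <- lapply(1:10, function(i) rand_clusters(3, label = paste0("s", i)))
  for (metric in c("emd", "chisq", "color", "weighted")) {
    m <- distance_matrix(sets, metric)
    expect_true(all(diag(m) == 0))
    expect_identical(unclass(m), t(unclass(m)))
    expect_true(all(m >= 0))
  }
  expect_error(distance_matrix(sets, "manhattan"), "valid metrics")
  expect_error(distance_matrix(sets[1]), "at least 2")

  dup <- distance_matrix(list(sets[[1]], sets[[1]]), "emd")
  expect_true(all(dup == 0))
})

test_that("RGB EMD normalizes to at most 1; Lab normalization is refused", {
  set.seed(65)
  sets <- lapply(1:6, function(i) rand_clusters(4, label = paste0("s", i)))
  m <- distance_matrix(sets, "emd", normalize = TRUE)
  expect_true(all(m <= 1 + 1e-12))
  expect_true(attr(m, "normalized"))

  lab_sets <- lapply(1:3, function(i) rand_clusters(3, "lab", paste0("l", i)))
  expect_warning(ml <- distance_matrix(lab_sets, "emd", normalize = TRUE),
                 "no absolute maximum")
  expect_false(attr(ml, "normalized"))
})

test_that("distance matrices round trip through CSV and TSV bit-exact", {
  set.seed(66)
  sets <- lapply(1:4, function(i) rand_clusters(3, label = paste0("img", i)))
  m <- distance_matrix(sets, "emd")
  for (sep in c(",", "\t")) {
    path <- tempfile(fileext = ".txt")
    write_distance_matrix(m, path, sep = sep)
    back <- read_distance_matrix(path, sep = sep)
    expect_equal(unclass(back), unclass(m), ignore_attr = TRUE)
    expect_identical(dimnames(back), dimnames(m))
    expect_identical(attr(back, "metric"), attr(m, "metric"))
  }
})
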