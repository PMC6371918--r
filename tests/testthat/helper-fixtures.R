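# Shared test helpers: tiny image builders, random cluster sets, and
# independent oracles (exhaustive assignment, closed-form 1D transport,
# scipy linear-program EMD).

# Build a height x width x 3 array from a row-major list of pixel colors.
make_img <- function(colors, height, width) {
  colors <- as.matrix(colors)
  stopifnot(nrow(colors) == height * width)
  img <- array(0, dim = c(height, width, 3))
  for (ch in 1:3) img[, , ch] <- matrix(colors[, ch], height, width, byrow = TRUE)
  img
}

# Solid or split square written to a temp PNG; returns the path.
write_tmp_png <- function(colors, height, width, name = "img") {
  path <- tempfile(name, fileext = ".png")
  png::writePNG(make_img(colors, height, width), path)
  path
}

solid_block <- function(color, n) matrix(rep(color, n), ncol = 3, byrow = TRUE)

# Random cluster set with normalized sizes (uses the internal constructor so
# distance metrics can be exercised without images).
rand_clusters <- function(k, space = "rgb", label = NA_character_,
                          method = "kmeans") {
  centers <- matrix(runif(3 * k), k, 3)
  if (space == "lab") {
    centers[, 1] <- centers[, 1] * 100
    centers[, 2:3] <- centers[, 2:3] * 255 - 128
  }
  sizes <- runif(k)
  sizes <- sizes / sum(sizes)
  chromadist:::color_clusters(centers, sizes, round(sizes * 1e4), space,
                              method, label = label,
                              n_source_pixels = 1e4)
}

# point mass profile at a single color
point_mass <- function(center, space = "rgb") {
  chromadist:::color_clusters(matrix(center, 1, 3), 1, 1000, space, "kmeans",
                              n_source_pixels = 1000)
}

# two-point mixture {a: 1-t, b: t}
two_point <- function(ca, cb, t, space = "rgb") {
  chromadist:::color_clusters(rbind(ca, cb), c(1 - t, t),
                              round(c(1 - t, t) * 1000), space, "kmeans",
                              n_source_pixels = 1000)
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Exhaustive minimum-cost bijective assignment.
brute_force_assignment <- function(cost) {
  k <- nrow(cost)
  best <- Inf
  best_perm <- NULL
  for (p in all_perms(k)) {
    cst <- sum(cost[cbind(seq_len(k), p)])
    if (cst < best) { best <- cst; best_perm <- p }
  }
  list(perm = best_perm, cost = best)
}

# Closed-form 1D Wasserstein-1 distance: integral of |CDF_a - CDF_b|.
emd_1d_oracle <- function(pos_a, w_a, pos_b, w_b) {
  pts <- sort(unique(c(pos_a, pos_b)))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    fa <- sum(w_a[pos_a <= pts[i]])
    fb <- sum(w_b[pos_b <= pts[i]])
    total <- total + abs(fa - fb) * (pts[i + 1L] - pts[i])
  }
  total
}

# Independent transportation-LP EMD via scipy (one python call for a batch).
# Each problem: list(sa, sb, ca, cb) with ca/cb k x 3 center matrices.
scipy_emd_batch <- function(problems) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(problems, infile, digits = NA)
  status <- suppressWarnings(system2(
    "python", c(testthat::test_path("lp_oracle.py"), infile, outfile),
    stdout = TRUE, stderr = TRUE))
  if (!file.exists(outfile)) {
    stop("scipy LP oracle failed: ", paste(status, collapse = "\n"))
  }
  as.numeric(unlist(jsonlite::read_json(outfile)))
}

emd_between <- function(a, b) {
  list(sa = a$sizes[a$sizes > 0], sb = b$sizes[b$sizes > 0],
       ca = a$centers[a$sizes > 0, , drop = FALSE],
       cb = b$centers[b$sizes > 0, , drop = FALSE])
}
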