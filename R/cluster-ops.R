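# Align cluster rows across images (minimum-cost bijective assignment) and
# average multiple cluster sets into one profile.

# Minimum-cost bijective assignment via the Hungarian method (clue::solve_LSAP),
# with an optional lexicographic refinement so that ties between equal-cost
# assignments are broken deterministically (lowest permutation wins).
min_assignment <- function(cost, lexicographic = TRUE) {
  k <- nrow(cost)
  if (k == 1L) return(list(perm = 1L, cost = cost[1, 1]))
  base <- as.integer(clue::solve_LSAP(cost))
  opt <- sum(cost[cbind(seq_len(k), base)])
  if (!lexicographic || k > 8L) return(list(perm = base, cost = opt))

  tol <- 1e-9 * max(1, abs(opt))
  big <- sum(abs(cost)) + 1
  work <- cost
  avail <- seq_len(k)
  perm <- integer(k)
  for (i in seq_len(k)) {
    for (j in sort(avail)) {
      trial <- work
      trial[i, setdiff(seq_len(k), j)] <- big
      sol <- as.integer(clue::solve_LSAP(trial))
      if (sum(cost[cbind(seq_len(k), sol)]) <= opt + tol) {
        perm[i] <- j
        work[i, setdiff(seq_len(k), j)] <- big
        avail <- setdiff(avail, j)
        break
      }
    }
  }
  list(perm = perm, cost = sum(cost[cbind(seq_len(k), perm)]))
}

check_compatible <- function(sets, same_method = TRUE) {
  if (!is.list(sets) || length(sets) < 1L ||
      !all(vapply(sets, inherits, logical(1), "color_clusters"))) {
    stop("`sets` must be a list of color_clusters", call. = FALSE)
  }
  k <- vapply(sets, function(s) length(s$sizes), integer(1))
  if (length(unique(k)) != 1L) {
    stop("cluster sets have different bin counts: ",
         paste(unique(k), collapse = ", "), call. = FALSE)
  }
  sp <- vapply(sets, function(s) s$space, character(1))
  if (length(unique(sp)) != 1L) {
    stop("cluster sets are in different color spaces: ",
         paste(unique(sp), collapse = ", "), call. = FALSE)
  }
  if (same_method &&
      length(unique(vapply(sets, function(s) s$method, character(1)))) != 1L) {
    stop("cluster sets mix binning methods", call. = FALSE)
  }
  invisible(k[1])
}

#' Align k-means clusters across images with the Hungarian algorithm
#'
#' k-means clusters come out in arbitrary order, so "row 1" of one image need
#' not be comparable to "row 1" of another. This permutes every set's bins by
#' the minimum-total-Euclidean-center-distance bijection to a reference set
#' (the set with the lexicographically smallest label), so matched rows hold
#' the most similar clusters across images -- dark with dark, orange with
#' orange -- before any positional metric is computed. Sizes travel with their
#' centers.
#'
#' Histogram sets share fixed bin boundaries and are already positionally
#' aligned; they are returned unchanged.
#'
#' @param sets a list of `color_clusters` with equal bin counts and one color
#'   space.
#' @return the list with bins permuted; the `"alignment"` attribute records the
#'   reference label, each image's permutation, and the total matched-center
#'   distance. Assignment cost uses center positions only (sizes are the
#'   business of the weighted metrics, not of the matching).
#' @export
order_clusters <- function(sets) {
  check_compatible(sets)
  if (all(vapply(sets, function(s) s$method, character(1)) == "hist")) {
    return(sets)
  }
  labels <- vapply(sets, function(s) s$label, character(1))
  ref_i <- if (all(is.na(labels))) 1L else order(labels)[1]
  ref <- sets[[ref_i]]

  perms <- vector("list", length(sets))
  total_cost <- 0
  out <- sets
  for (i in seq_along(sets)) {
    if (i == ref_i) { perms[[i]] <- seq_along(ref$sizes); next }
    cost <- pairwise_distances(ref$centers, sets[[i]]$centers)
    a <- min_assignment(cost)
    perms[[i]] <- a$perm
    total_cost <- total_cost + a$cost
    out[[i]]$centers <- sets[[i]]$centers[a$perm, , drop = FALSE]
    out[[i]]$sizes <- sets[[i]]$sizes[a$perm]
    out[[i]]$counts <- sets[[i]]$counts[a$perm]
  }
  names(perms) <- labels
  attr(out, "alignment") <- list(reference_label = ref$label,
                                 permutations = perms,
                                 total_cost = total_cost)
  out
}

#' Average several aligned cluster sets into one profile
#'
#' For each matched bin, the combined size is the mean of the per-image sizes
#' (each image weighs equally regardless of resolution) and the combined
#' center is the pixel-count-weighted mean of the per-image centers (set
#' `center_weights = "equal"` to weigh images equally there too). Bins empty in
#' every image fall back to the geometric bin midpoint when bounds are known.
#' Use this to build one profile per species/site/category from replicate
#' photographs before computing a distance matrix.
#'
#' @param sets aligned `color_clusters` (same k, space, method; histogram sets
#'   must share one bin spec).
#' @param center_weights `"count"` (default) or `"equal"`.
#' @return a single `color_clusters`; sizes sum to 1.
#' @export
combine_cluster_sets <- function(sets, center_weights = c("count", "equal")) {
  center_weights <- match.arg(center_weights)
  k <- check_compatible(sets)
  if (sets[[1]]$method == "hist") {
    for (s in sets[-1]) {
      if (!isTRUE(all.equal(s$bin_lower, sets[[1]]$bin_lower)) ||
          !isTRUE(all.equal(s$bin_upper, sets[[1]]$bin_upper))) {
        stop("histogram sets use different bin boundaries", call. = FALSE)
      }
    }
  }
  sizes <- rowMeans(matrix(vapply(sets, function(s) s$sizes, numeric(k)), k))
  counts <- rowSums(matrix(vapply(sets, function(s) s$counts, numeric(k)), k))
  centers <- matrix(0, k, 3)
  for (b in seq_len(k)) {
    w <- vapply(sets, function(s) {
      if (center_weights == "count") s$counts[b] else as.numeric(s$counts[b] > 0)
    }, numeric(1))
    if (sum(w) > 0) {
      ctr <- t(vapply(sets, function(s) s$centers[b, ], numeric(3)))
      centers[b, ] <- colSums(ctr * w) / sum(w)
    } else if (!is.null(sets[[1]]$bin_lower)) {
      centers[b, ] <- (sets[[1]]$bin_lower[b, ] + sets[[1]]$bin_upper[b, ]) / 2
    } else {
      centers[b, ] <- sets[[1]]$centers[b, ]
    }
  }
  color_clusters(centers, sizes, counts, sets[[1]]$space, sets[[1]]$method,
                 label = paste0("combined(",
                                paste(vapply(sets, function(s) s$label,
                                             character(1)), collapse = "+"), ")"),
                 n_source_pixels = sum(vapply(sets, function(s) s$n_source_pixels,
                                              numeric(1))),
                 bin_lower = sets[[1]]$bin_lower,
                 bin_upper = sets[[1]]$bin_upper,
                 ref_white = sets[[1]]$ref_white)
}
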