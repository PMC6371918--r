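# Pairwise color distances between cluster sets, and labeled distance matrices.

# Euclidean distances between rows of a and rows of b, computed
# difference-first so coincident points yield exactly zero.
pairwise_distances <- function(a, b) {
  m <- nrow(a); n <- nrow(b)
  out <- matrix(0, m, n)
  for (j in seq_len(n)) {
    out[, j] <- sqrt(rowSums((a - matrix(b[j, ], m, ncol(b), byrow = TRUE))^2))
  }
  out
}

check_pair <- function(a, b, positional = FALSE) {
  if (!inherits(a, "color_clusters") || !inherits(b, "color_clusters")) {
    stop("both arguments must be color_clusters", call. = FALSE)
  }
  if (a$space != b$space) {
    stop("cluster sets are in different color spaces (", a$space, " vs ",
         b$space, ")", call. = FALSE)
  }
  if (positional && length(a$sizes) != length(b$sizes)) {
    stop("cluster sets have different bin counts (", length(a$sizes), " vs ",
         length(b$sizes), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Earth mover's distance between two color profiles
#'
#' Treats each cluster set as a distribution of mass (bin sizes) over points
#' in color space (bin centers) and returns the minimum total cost of
#' transporting one distribution onto the other, with Euclidean distance
#' between centers as the per-unit cost. Moving a lot of mass, or moving it
#' far, both raise the score, so EMD reflects differences in color amount
#' *and* color similarity at once; it is the recommended default metric.
#' Sizes are normalized to total mass 1, so in RGB or HSV space the score is
#' bounded by the unit-cube diagonal, sqrt(3).
#'
#' @param a,b `color_clusters` in the same color space (any bin counts; bins
#'   need not be aligned -- the transport plan does the matching).
#' @param return_plan if `TRUE`, attach the optimal [solve_transport()] plan
#'   (computed over the nonempty bins) as the `"plan"` attribute.
#' @return nonnegative distance (a metric over normalized profiles).
#' @details Empty bins carry no mass and are excluded from the transport
#'   problem; they influence EMD not at all (unlike [chi_squared_distance()],
#'   where position in the bin list is everything).
#' @export
emd <- function(a, b, return_plan = FALSE) {
  check_pair(a, b)
  ia <- a$sizes > 0; ib <- b$sizes > 0
  if (!any(ia) || !any(ib)) stop("cannot compute EMD for an all-empty profile",
                                 call. = FALSE)
  sa <- a$sizes[ia] / sum(a$sizes[ia])
  sb <- b$sizes[ib] / sum(b$sizes[ib])
  ca <- a$centers[ia, , drop = FALSE]
  cb <- b$centers[ib, , drop = FALSE]
  ground <- pairwise_distances(ca, cb)
  plan <- solve_transport(sa, sb, ground)
  if (return_plan) return(structure(plan$cost, plan = plan))
  plan$cost
}

#' Chi-squared distance between two aligned profiles
#'
#' `sum((s_a - s_b)^2 / (s_a + s_b))` over positionally matched bins; terms
#' with an empty bin in both profiles contribute 0. Centers are ignored
#' entirely, so two profiles of identical proportions in *different* colors
#' score 0 -- an all-black and an all-gray image can look identical to this
#' metric if their pixels land in the same bins. Use it when bins are known to
#' be comparable (shared histogram spec, or k-means after [order_clusters()]).
#'
#' @param a,b `color_clusters` with equal bin counts and aligned bin semantics.
#' @return nonnegative distance.
#' @export
chi_squared_distance <- function(a, b) {
  check_pair(a, b, positional = TRUE)
  num <- (a$sizes - b$sizes)^2
  den <- a$sizes + b$sizes
  sum(ifelse(den > 0, num / den, 0))
}

#' Mean center-to-center color distance, ignoring bin sizes
#'
#' The average Euclidean distance between positionally matched bin centers.
#' Sensitive only to *which* colors appear, not how much of each.
#'
#' @inheritParams chi_squared_distance
#' @return nonnegative distance.
#' @export
color_distance <- function(a, b) {
  check_pair(a, b, positional = TRUE)
  mean(sqrt(rowSums((a$centers - b$centers)^2)))
}

#' Weighted combination of size and center differences
#'
#' Per matched bin pair, `color_weight * ||center_a - center_b|| +
#' size_weight * |size_a - size_b|`, averaged over bins. With
#' `color_weight = 1` this reduces to [color_distance()].
#'
#' @inheritParams chi_squared_distance
#' @param size_weight,color_weight nonnegative weights summing to 1.
#' @return nonnegative distance.
#' @export
weighted_pair_distance <- function(a, b, size_weight = 0.5,
                                   color_weight = 1 - size_weight) {
  check_pair(a, b, positional = TRUE)
  if (size_weight < 0 || color_weight < 0 ||
      abs(size_weight + color_weight - 1) > 1e-9) {
    stop("size_weight and color_weight must be nonnegative and sum to 1",
         call. = FALSE)
  }
  ctr <- sqrt(rowSums((a$centers - b$centers)^2))
  mean(color_weight * ctr + size_weight * abs(a$sizes - b$sizes))
}

DISTANCE_METRICS <- c("emd", "chisq", "color", "weighted")

#' Pairwise color distance matrix for a set of images
#'
#' Computes the chosen metric for every pair of cluster sets and returns a
#' labeled symmetric matrix with a zero diagonal -- the end product of a
#' chromadist analysis, ready for clustering, ordination, or comparative
#' statistics.
#'
#' @param sets a list of >= 2 mutually compatible `color_clusters` (run
#'   [order_clusters()] first for k-means sets).
#' @param metric `"emd"` (default), `"chisq"`, `"color"`, or `"weighted"`.
#' @param normalize if `TRUE` (default) and the space is RGB or HSV and the
#'   metric is EMD, divide by sqrt(3) -- the maximum possible score, the cost
#'   of moving all mass across the unit cube's diagonal -- so scores land in
#'   [0, 1]. CIE Lab has no absolute maximum EMD, so in Lab the flag is
#'   ignored with a warning and raw scores are returned.
#' @param size_weight passed to [weighted_pair_distance()] when
#'   `metric = "weighted"`.
#' @return a `color_distance_matrix`: a numeric matrix with image labels as
#'   dimnames and attributes `metric`, `normalized`, and `space`.
#' @export
distance_matrix <- function(sets, metric = c("emd", "chisq", "color", "weighted"),
                            normalize = TRUE, size_weight = 0.5) {
  if (is.character(metric) && length(metric) == 1L &&
      !metric %in% DISTANCE_METRICS) {
    stop("unknown metric '", metric, "'; valid metrics: ",
         paste(DISTANCE_METRICS, collapse = ", "), call. = FALSE)
  }
  metric <- match.arg(metric)
  if (length(sets) < 2L) stop("need at least 2 cluster sets", call. = FALSE)
  check_compatible(sets, same_method = FALSE)
  space <- sets[[1]]$space

  normalized <- FALSE
  scale <- 1
  if (normalize && metric == "emd") {
    if (space %in% c("rgb", "hsv")) {
      scale <- sqrt(3)
      normalized <- TRUE
    } else {
      warning("no absolute maximum EMD score in CIE Lab space; ",
              "returning unnormalized distances", call. = FALSE)
    }
  }

  labels <- vapply(sets, function(s) s$label, character(1))
  if (any(is.na(labels))) labels[is.na(labels)] <-
      paste0("image", which(is.na(labels)))
  n <- length(sets)
  fun <- switch(metric,
                emd = emd,
                chisq = chi_squared_distance,
                color = color_distance,
                weighted = function(a, b) weighted_pair_distance(a, b, size_weight))
  values <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      values[i, j] <- values[j, i] <- fun(sets[[i]], sets[[j]]) / scale
    }
  }
  structure(values, metric = metric, normalized = normalized, space = space,
            class = c("color_distance_matrix", class(values)))
}

#' @export
print.color_distance_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Color distance matrix (%s%s, %s space), %d images:\n",
              attr(x, "metric"),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else "",
              toupper(attr(x, "space")), nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' @export
plot.color_distance_matrix <- function(x, ...) {
  render_heatmap(x, outfile = NULL, ...)
}

#' Write a distance matrix to disk (and read it back)
#'
#' `write_distance_matrix` writes CSV with labels in the first row and column
#' (or a square tab-separated dialect when `sep = "\t"`), plus `#`-prefixed
#' metadata lines; values go out at full double precision so a round trip is
#' bit-exact.
#'
#' @param mat a `color_distance_matrix`.
#' @param path output path.
#' @param sep `","` (default) or `"\t"`.
#' @return `path` invisibly; `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(mat, path, sep = ",") {
  stopifnot(inherits(mat, "color_distance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# metric: ", attr(mat, "metric")),
               paste0("# normalized: ", isTRUE(attr(mat, "normalized"))),
               paste0("# space: ", attr(mat, "space"))), con)
  body <- format(unclass(mat), digits = 17, trim = TRUE, scientific = TRUE)
  writeLines(paste(c("", colnames(mat)), collapse = sep), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], body[i, ]), collapse = sep), con)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, sep = ",") {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in meta_lines) {
    kv <- strsplit(sub("^# ", "", h), ": ", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  tab <- read.table(text = lines[!startsWith(lines, "# ")], sep = sep,
                    header = TRUE, row.names = 1, check.names = FALSE)
  values <- as.matrix(tab)
  structure(values, metric = meta$metric,
            normalized = identical(meta$normalized, "TRUE"),
            space = meta$space,
            class = c("color_distance_matrix", class(values)))
}
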