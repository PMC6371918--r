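# Reduce a pixel set to a weighted set of color clusters, either by
# fixed-boundary 3D histogram binning or by k-means clustering.

default_channel_bounds <- function(space) {
  switch(space,
         rgb = ,
         hsv = list(c(0, 1), c(0, 1), c(0, 1)),
         lab = list(c(0, 100), c(-128, 127), c(-128, 127)),
         stop("unknown color space: ", space, call. = FALSE))
}

check_channel_bounds <- function(channel_bounds, space) {
  if (is.null(channel_bounds)) channel_bounds <- default_channel_bounds(space)
  if (is.matrix(channel_bounds)) {
    channel_bounds <- lapply(seq_len(nrow(channel_bounds)),
                             function(i) channel_bounds[i, ])
  }
  if (!is.list(channel_bounds) || length(channel_bounds) != 3L) {
    stop("`channel_bounds` must give [min, max] for each of 3 channels",
         call. = FALSE)
  }
  for (i in 1:3) {
    b <- as.numeric(channel_bounds[[i]])
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop("channel_bounds[[", i, "]] must be finite with min < max",
           call. = FALSE)
    }
    channel_bounds[[i]] <- b
  }
  names(channel_bounds) <- channel_names(space)
  channel_bounds
}

# Constructor shared by both binning methods and the CSV reader.
color_clusters <- function(centers, sizes, counts, space, method,
                           label = NA_character_, n_source_pixels = sum(counts),
                           bin_lower = NULL, bin_upper = NULL,
                           ref_white = NULL, seed = NULL) {
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  colnames(centers) <- channel_names(space)
  structure(list(centers = centers, sizes = as.numeric(sizes),
                 counts = as.numeric(counts), space = space, method = method,
                 label = label, n_source_pixels = n_source_pixels,
                 bin_lower = bin_lower, bin_upper = bin_upper,
                 ref_white = ref_white, seed = seed),
            class = "color_clusters")
}

#' @export
print.color_clusters <- function(x, digits = 4, ...) {
  cat(sprintf("<color_clusters> %s, %d bins, %s space%s\n",
              x$method, length(x$sizes), toupper(x$space),
              if (!is.na(x$label)) paste0("  [", x$label, "]") else ""))
  print(round(as.data.frame(x), digits))
  invisible(x)
}

#' @export
as.data.frame.color_clusters <- function(x, ...) {
  df <- as.data.frame(x$centers)
  df$size <- x$sizes
  df$count <- x$counts
  df
}

# Render cluster centers as displayable sRGB colors.
cluster_colors <- function(x) {
  ctr <- x$centers
  rgb <- switch(x$space,
                rgb = ctr,
                hsv = hsv_to_rgb_matrix(ctr),
                lab = pmin(pmax(lab_to_rgb_matrix(
                  ctr, reference_white(x$ref_white %||% "D65")), 0), 1))
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3])
}

#' @export
plot.color_clusters <- function(x, ...) {
  graphics::barplot(x$sizes, col = cluster_colors(x), border = NA,
                    names.arg = seq_along(x$sizes),
                    xlab = "bin", ylab = "proportion of object pixels",
                    main = x$label %||% "", ...)
  invisible(x)
}

#' Bin pixels into a fixed-boundary 3D color histogram
#'
#' Each channel's range is divided into `bins[i]` equal intervals, half-open
#' `[low, high)` with the top interval closed at the channel maximum, so that
#' every pixel belongs to exactly one of `prod(bins)` boxes. A bin's center is
#' the mean of its member pixels (the geometric midpoint of the box when the
#' bin is empty) and its size is the proportion of object pixels it holds.
#' Because the boxes are identical for every image, bins are positionally
#' comparable across images; they are emitted with the first channel's index
#' varying fastest.
#'
#' @param pixels a `pixel_set` in any supported space.
#' @param bins integer(3) (or a single integer recycled) giving bins per
#'   channel; default `c(3, 3, 3)` = 27 bins.
#' @param channel_bounds list of three `[min, max]` pairs. Defaults: 0-1 for
#'   RGB/HSV; L 0-100, a and b -128-127 for Lab (the range RGB-derived colors
#'   occupy in practice). Restricting the a/b bounds to the range actually
#'   exhibited by an image set concentrates bins where the data are.
#' @param label identifier carried into distance matrices.
#' @return a `color_clusters` object (`method = "hist"`).
#' @details Pixels outside `channel_bounds` raise an error naming the channel
#'   and the observed range, rather than being silently clamped: when bounds
#'   are user-restricted they are a contract that the data are enclosed.
#' @export
histogram_bin <- function(pixels, bins = c(3, 3, 3), channel_bounds = NULL,
                          label = NA_character_) {
  stopifnot(inherits(pixels, "pixel_set"))
  coords <- pixels$coords
  n <- nrow(coords)
  if (n < 1L) stop("cannot bin an empty pixel set", call. = FALSE)
  bins <- as.integer(bins)
  if (length(bins) == 1L) bins <- rep(bins, 3L)
  if (length(bins) != 3L || any(bins < 1L)) {
    stop("`bins` must be 1 or 3 positive integers", call. = FALSE)
  }
  bounds <- check_channel_bounds(channel_bounds, pixels$space)

  idx3 <- matrix(0L, n, 3)
  for (ch in 1:3) {
    lo <- bounds[[ch]][1]; hi <- bounds[[ch]][2]
    x <- coords[, ch]
    if (any(x < lo) || any(x > hi)) {
      stop(sprintf(
        "pixels outside channel bounds: %s spans [%.6g, %.6g] but bounds are [%g, %g]",
        channel_names(pixels$space)[ch], min(x), max(x), lo, hi),
        call. = FALSE)
    }
    width <- (hi - lo) / bins[ch]
    idx3[, ch] <- pmin(floor((x - lo) / width) + 1L, bins[ch])
  }
  # linear bin index, channel 1 fastest
  lin <- idx3[, 1] + bins[1] * (idx3[, 2] - 1L) + bins[1] * bins[2] * (idx3[, 3] - 1L)

  k <- prod(bins)
  counts <- tabulate(lin, nbins = k)
  part <- rowsum(coords, lin)
  sums <- matrix(0, k, 3)
  sums[as.integer(rownames(part)), ] <- part
  grid <- expand.grid(i1 = seq_len(bins[1]), i2 = seq_len(bins[2]),
                      i3 = seq_len(bins[3]))
  lower <- upper <- matrix(0, k, 3)
  for (ch in 1:3) {
    lo <- bounds[[ch]][1]
    width <- (bounds[[ch]][2] - lo) / bins[ch]
    lower[, ch] <- lo + (grid[[ch]] - 1) * width
    upper[, ch] <- lo + grid[[ch]] * width
  }
  centers <- (lower + upper) / 2
  filled <- counts > 0
  centers[filled, ] <- sums[filled, , drop = FALSE] / counts[filled]

  color_clusters(centers, counts / n, counts, pixels$space, "hist",
                 label = label, n_source_pixels = n,
                 bin_lower = lower, bin_upper = upper,
                 ref_white = attr(pixels, "ref_white"))
}

# squared Euclidean distances between rows of x (n x 3) and centers (k x 3)
sqdist_to_centers <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers^2)) - 2 * x %*% t(centers)
}

kmeanspp_init <- function(coords, k) {
  n <- nrow(coords)
  centers <- matrix(0, k, ncol(coords))
  centers[1, ] <- coords[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(coords, 2, centers[1, ])^2)
    for (i in 2:k) {
      if (sum(d2) <= 0) {
        centers[i, ] <- coords[sample.int(n, 1L), ]
      } else {
        centers[i, ] <- coords[sample.int(n, 1L, prob = d2), ]
      }
      d2 <- pmin(d2, rowSums(sweep(coords, 2, centers[i, ])^2))
    }
  }
  centers
}

lloyd_kmeans <- function(coords, centers, max_iter = 100L) {
  k <- nrow(centers)
  assign_old <- rep(0L, nrow(coords))
  for (it in seq_len(max_iter)) {
    d2 <- sqdist_to_centers(coords, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {        # re-seed a cluster that lost all members
      if (!any(assign_new == j)) {
        far <- which.max(d2[cbind(seq_len(nrow(coords)), assign_new)])
        centers[j, ] <- coords[far, ]
        assign_new[far] <- j
      }
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    part <- rowsum(coords, assign_new)
    centers <- matrix(0, k, ncol(coords))
    centers[as.integer(rownames(part)), ] <- part
    centers <- centers / tabulate(assign_new, nbins = k)
  }
  d2 <- sqdist_to_centers(coords, centers)
  assignment <- max.col(-d2, ties.method = "first")
  wcss <- sum(d2[cbind(seq_along(assignment), assignment)])
  list(centers = centers, assignment = assignment, wcss = wcss)
}

#' Cluster pixels into k dominant colors with k-means
#'
#' Lloyd's algorithm with k-means++ seeding, run `restarts` times; the
#' solution with the lowest within-cluster sum of squares wins. A center that
#' loses all members during iteration is re-seeded at the pixel farthest from
#' its current center, so exactly `k` clusters are always returned. Results
#' are deterministic for a fixed `seed`.
#'
#' @param pixels a `pixel_set`.
#' @param k number of clusters; must not exceed the number of distinct pixel
#'   colors.
#' @param seed RNG seed for the restarts (recorded in the result).
#' @param restarts number of seeded initializations (default 10).
#' @param label identifier carried into distance matrices.
#' @return a `color_clusters` object (`method = "kmeans"`) with centers equal
#'   to cluster means and sizes equal to member proportions.
#' @export
kmeans_bin <- function(pixels, k, seed = 1L, restarts = 10L,
                       label = NA_character_) {
  stopifnot(inherits(pixels, "pixel_set"))
  coords <- pixels$coords
  n <- nrow(coords)
  if (k < 1L) stop("`k` must be at least 1", call. = FALSE)
  n_distinct <- nrow(unique(coords))
  if (n_distinct < k) {
    stop("only ", n_distinct, " distinct pixel colors but k = ", k,
         "; choose a smaller k", call. = FALSE)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- lloyd_kmeans(coords, kmeanspp_init(coords, k))
      if (is.null(best) || fit$wcss < best$wcss - 1e-12) best <- fit
    }
  })
  counts <- tabulate(best$assignment, nbins = k)
  color_clusters(best$centers, counts / n, counts, pixels$space, "kmeans",
                 label = label, n_source_pixels = n,
                 ref_white = attr(pixels, "ref_white"), seed = seed)
}

#' Bin every image in a set with one shared configuration
#'
#' Loads each image, masks the background, optionally converts color space
#' (subsampling very large pixel sets before Lab conversion), and bins with
#' the same spec, so the resulting profiles are mutually comparable. Images
#' are processed in sorted path order and labeled by file stem.
#'
#' @param paths a directory containing PNG/JPEG files, or a vector of file
#'   paths (at least 2 for downstream distance matrices).
#' @param method `"hist"` (default) or `"kmeans"`.
#' @param color_space `"rgb"` (default), `"hsv"`, or `"lab"`.
#' @param white illuminant for Lab conversion.
#' @param background a [background_range()] or list of them; `NULL` keeps all
#'   pixels.
#' @param bins bins per channel for the histogram method.
#' @param channel_bounds see [histogram_bin()].
#' @param k,restarts,seed see [kmeans_bin()].
#' @param sample_limit pixel cap before color conversion (see
#'   [sample_pixels()]); `Inf` disables sampling.
#' @return a named list of `color_clusters`, one per image.
#' @details If any image fails, all images are still attempted and a single
#'   error lists every failing file.
#' @export
bin_image_set <- function(paths, method = c("hist", "kmeans"),
                          color_space = c("rgb", "hsv", "lab"), white = "D65",
                          background = background_range(c(0, 0.6, 0),
                                                        c(0.4, 1, 0.4)),
                          bins = c(3, 3, 3), channel_bounds = NULL,
                          k = 3L, restarts = 10L, seed = 1L,
                          sample_limit = 1e5) {
  method <- match.arg(method)
  color_space <- match.arg(color_space)
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
  }
  if (length(paths) == 0L) stop("no PNG or JPEG images found", call. = FALSE)
  paths <- sort(paths)
  labels <- tools::file_path_sans_ext(basename(paths))

  out <- vector("list", length(paths))
  failures <- character(0)
  for (i in seq_along(paths)) {
    res <- tryCatch({
      px <- load_image(paths[i], background)$pixels
      if (is.finite(sample_limit)) px <- sample_pixels(px, sample_limit, seed)
      px <- convert_color_space(px, color_space, white)
      if (method == "hist") {
        histogram_bin(px, bins, channel_bounds, label = labels[i])
      } else {
        kmeans_bin(px, k, seed = seed, restarts = restarts, label = labels[i])
      }
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<-
        paste0(paths[i], ": ", conditionMessage(e))
      NULL
    })
    out[[i]] <- res
  }
  if (length(failures)) {
    stop("failed to process ", length(failures), " image(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  names(out) <- labels
  out
}

#' Write a cluster set to CSV (and read it back)
#'
#' The interchange format: one column per channel, then `size` and `count`,
#' preceded by `#`-prefixed header lines recording the space, method, label,
#' source pixel count, and (for histograms) the bin bounds. Doubles are
#' written at full precision so a round trip is bit-exact.
#'
#' @param clusters a `color_clusters` object.
#' @param path output CSV path.
#' @return `path` invisibly (`write_clusters`); a `color_clusters`
#'   (`read_clusters`).
#' @export
write_clusters <- function(clusters, path) {
  stopifnot(inherits(clusters, "color_clusters"))
  num <- function(v) format(v, digits = 17, trim = TRUE, scientific = TRUE)
  hdr <- c(paste0("# space: ", clusters$space),
           paste0("# method: ", clusters$method),
           paste0("# label: ", clusters$label),
           paste0("# n_source_pixels: ", clusters$n_source_pixels))
  if (!is.null(clusters$ref_white)) {
    hdr <- c(hdr, paste0("# ref_white: ", clusters$ref_white))
  }
  if (!is.null(clusters$bin_lower)) {
    hdr <- c(hdr,
             paste0("# bin_lower: ", paste(num(clusters$bin_lower), collapse = " ")),
             paste0("# bin_upper: ", paste(num(clusters$bin_upper), collapse = " ")))
  }
  body <- cbind(apply(clusters$centers, 2, num), size = num(clusters$sizes),
                count = num(clusters$counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(body), collapse = ","), con)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (h in hdr_lines) {
    kv <- sub("^# ([^:]+): (.*)$", "\\1\x01\\2", h)
    kv <- strsplit(kv, "\x01", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  df <- read.csv(text = lines[!startsWith(lines, "# ")],
                 check.names = FALSE)
  k <- nrow(df)
  lower <- upper <- NULL
  if (!is.null(meta$bin_lower)) {
    lower <- matrix(as.numeric(strsplit(meta$bin_lower, " ")[[1]]), k, 3)
    upper <- matrix(as.numeric(strsplit(meta$bin_upper, " ")[[1]]), k, 3)
  }
  color_clusters(as.matrix(df[, 1:3]), df$size, df$count,
                 space = meta$space, method = meta$method,
                 label = if (identical(meta$label, "NA")) NA_character_ else meta$label,
                 n_source_pixels = as.numeric(meta$n_source_pixels),
                 bin_lower = lower, bin_upper = upper,
                 ref_white = meta$ref_white)
}
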