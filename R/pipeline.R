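# One-command pipeline from an image directory to a distance matrix with
# reports, plus the plotting helpers it uses.

HEATMAP_CAVEAT <- paste(
  "The heatmap's hierarchical clustering is intended as a visual tool for",
  "inspecting the results, not as a formal grouping of the images.")

#' Assemble and validate a pipeline configuration
#'
#' Every field is validated against its module's contract *before* any image
#' is read, so a typo fails fast. The same fields can be stored in a flat
#' `key: value` text file ([read_pipeline_config()]) and overridden by
#' arguments.
#'
#' @param input image directory or vector of image paths.
#' @param color_space `"rgb"`, `"hsv"`, or `"lab"`.
#' @param ref_white illuminant name for Lab conversion (see
#'   [reference_white()]).
#' @param background_lower,background_upper RGB triplets bounding the
#'   chroma-key background (inclusive), or `NULL` for no masking.
#' @param method `"hist"` or `"kmeans"`.
#' @param bins bins per channel for the histogram method.
#' @param k cluster count for the k-means method.
#' @param a_bounds,b_bounds optional `[min, max]` restrictions of the Lab a/b
#'   channels (histogram method).
#' @param metric one of `"emd"`, `"chisq"`, `"color"`, `"weighted"`.
#' @param size_weight weight on size differences for the weighted metric.
#' @param normalize divide RGB/HSV EMD scores by sqrt(3).
#' @param seed RNG seed for subsampling and k-means restarts.
#' @param sample_limit pixel cap before color conversion.
#' @param linkage hclust linkage used to order the heatmap (default
#'   `"complete"`).
#' @param out output directory for artifact files, or `NULL` for none.
#' @return a validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input, color_space = "rgb", ref_white = "D65",
                            background_lower = c(0, 0.6, 0),
                            background_upper = c(0.4, 1, 0.4),
                            method = "hist", bins = c(3, 3, 3), k = 3L,
                            a_bounds = NULL, b_bounds = NULL,
                            metric = "emd", size_weight = 0.5,
                            normalize = TRUE, seed = 1L, sample_limit = 1e5,
                            linkage = "complete", out = NULL) {
  color_space <- match.arg(color_space, c("rgb", "hsv", "lab"))
  method <- match.arg(method, c("hist", "kmeans"))
  if (!metric %in% DISTANCE_METRICS) {
    stop("unknown metric '", metric, "'; valid metrics: ",
         paste(DISTANCE_METRICS, collapse = ", "), call. = FALSE)
  }
  white <- reference_white(ref_white)
  background <- if (is.null(background_lower) || is.null(background_upper)) {
    NULL
  } else {
    background_range(background_lower, background_upper)
  }
  bins <- as.integer(bins)
  if (any(bins < 1L)) stop("`bins` must be positive", call. = FALSE)
  if (k < 1L) stop("`k` must be positive", call. = FALSE)
  linkage <- match.arg(linkage, c("complete", "single", "average", "ward.D2"))

  channel_bounds <- NULL
  if (!is.null(a_bounds) || !is.null(b_bounds)) {
    if (color_space != "lab") {
      stop("a_bounds/b_bounds apply only to Lab color space", call. = FALSE)
    }
    channel_bounds <- default_channel_bounds("lab")
    if (!is.null(a_bounds)) channel_bounds[[2]] <- as.numeric(a_bounds)
    if (!is.null(b_bounds)) channel_bounds[[3]] <- as.numeric(b_bounds)
    channel_bounds <- check_channel_bounds(channel_bounds, "lab")
  }

  structure(list(input = input, color_space = color_space,
                 ref_white = white$name, background = background,
                 method = method, bins = bins, k = as.integer(k),
                 channel_bounds = channel_bounds, metric = metric,
                 size_weight = size_weight, normalize = isTRUE(normalize),
                 seed = as.integer(seed), sample_limit = sample_limit,
                 linkage = linkage, out = out),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key: value file
#'
#' One `key: value` per line; keys are the argument names of
#' [pipeline_config()]; vector values are comma-separated
#' (e.g. `bins: 3,3,3`). Lines starting with `#` are comments. Arguments in
#' `...` override file values, mirroring how command-line flags override a
#' config file.
#'
#' @param path config file path.
#' @param ... overrides passed on to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  args <- list()
  numeric_keys <- c("background_lower", "background_upper", "bins", "k",
                    "a_bounds", "b_bounds", "size_weight", "seed",
                    "sample_limit")
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = ":"))
    args[[key]] <- if (key %in% numeric_keys) {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (key == "normalize") {
      toupper(val) %in% c("TRUE", "YES", "1")
    } else val
  }
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(pipeline_config, args)
}

#' Run the whole analysis: images in, distance matrix out
#'
#' Loads and masks every image, converts color space, bins, aligns k-means
#' clusters across images, and computes the pairwise distance matrix. When an
#' output directory is given it also writes the matrix CSV
#' (`distance_matrix.csv`), one cluster CSV per image (`clusters/`), a
#' clustered heatmap (`heatmap.png`), and a run-metadata record
#' (`run_metadata.txt`: all parameters, seeds, package version). Fixed
#' configuration and seed give byte-identical matrix CSVs across runs. If any
#' stage fails, files already written for this run are removed.
#'
#' @param input image directory, vector of image paths, or a ready
#'   [pipeline_config()] (in which case `...` still overrides fields).
#' @param ... arguments of [pipeline_config()].
#' @return the `color_distance_matrix`.
#' @export
image_cluster_pipeline <- function(input, ...) {
  config <- if (inherits(input, "pipeline_config")) {
    overrides <- list(...)
    if (length(overrides)) {
      fields <- unclass(input)
      bg <- fields$background
      cb <- fields$channel_bounds
      fields["background_lower"] <- list(if (is.null(bg)) NULL else bg$lower)
      fields["background_upper"] <- list(if (is.null(bg)) NULL else bg$upper)
      fields["a_bounds"] <- list(if (is.null(cb)) NULL else cb[[2]])
      fields["b_bounds"] <- list(if (is.null(cb)) NULL else cb[[3]])
      fields$background <- NULL
      fields$channel_bounds <- NULL
      fields[names(overrides)] <- overrides
      do.call(pipeline_config, fields)
    } else input
  } else {
    pipeline_config(input, ...)
  }

  written <- character(0)
  result <- tryCatch({
    sets <- bin_image_set(config$input, method = config$method,
                          color_space = config$color_space,
                          white = config$ref_white,
                          background = config$background,
                          bins = config$bins,
                          channel_bounds = config$channel_bounds,
                          k = config$k, seed = config$seed,
                          sample_limit = config$sample_limit)
    if (config$method == "kmeans") sets <- order_clusters(sets)
    mat <- distance_matrix(sets, metric = config$metric,
                           normalize = config$normalize,
                           size_weight = config$size_weight)

    if (!is.null(config$out)) {
      dir.create(file.path(config$out, "clusters"), showWarnings = FALSE,
                 recursive = TRUE)
      f <- file.path(config$out, "distance_matrix.csv")
      write_distance_matrix(mat, f); written <- c(written, f)
      for (s in sets) {
        f <- file.path(config$out, "clusters", paste0(s$label, ".csv"))
        write_clusters(s, f); written <- c(written, f)
      }
      f <- file.path(config$out, "heatmap.png")
      render_heatmap(mat, f, linkage = config$linkage); written <- c(written, f)
      f <- file.path(config$out, "run_metadata.txt")
      write_run_metadata(config, mat, f); written <- c(written, f)
    }
    mat
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  result
}

write_run_metadata <- function(config, mat, path) {
  bg <- config$background
  lines <- c(
    paste0("package: chromadist ",
           as.character(utils::packageVersion("chromadist"))),
    paste0("r_version: ", R.version.string),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("input: ", paste(config$input, collapse = ", ")),
    paste0("color_space: ", config$color_space),
    paste0("ref_white: ", config$ref_white),
    paste0("background_lower: ",
           if (is.null(bg)) "none" else paste(bg$lower, collapse = ",")),
    paste0("background_upper: ",
           if (is.null(bg)) "none" else paste(bg$upper, collapse = ",")),
    paste0("method: ", config$method),
    paste0("bins: ", paste(config$bins, collapse = ",")),
    paste0("k: ", config$k),
    paste0("metric: ", config$metric),
    paste0("normalize: ", config$normalize),
    paste0("normalized_applied: ", isTRUE(attr(mat, "normalized"))),
    paste0("seed: ", config$seed),
    paste0("sample_limit: ", format(config$sample_limit)),
    paste0("linkage: ", config$linkage),
    paste0("images: ", paste(rownames(mat), collapse = ", ")),
    paste0("note: ", HEATMAP_CAVEAT))
  if (!is.null(config$channel_bounds)) {
    lines <- c(lines,
               paste0("a_bounds: ", paste(config$channel_bounds[[2]], collapse = ",")),
               paste0("b_bounds: ", paste(config$channel_bounds[[3]], collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Draw a distance matrix as a heatmap ordered by hierarchical clustering
#'
#' Rows and columns are ordered by `hclust` on the distance matrix itself
#' (complete linkage by default) and the dendrogram is drawn alongside. The
#' clustering is a visual aid for spotting groups of similar images; treat it
#' as exploratory, not as a formal classification.
#'
#' @param mat a `color_distance_matrix` (or any labeled symmetric matrix).
#' @param outfile PNG path, or `NULL` to draw on the current device.
#' @param linkage `hclust` method (default `"complete"`).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return invisibly, a list with the `hclust` tree and the leaf `order`.
#' @export
render_heatmap <- function(mat, outfile = NULL, linkage = "complete", ...) {
  tree <- stats::hclust(stats::as.dist(mat), method = linkage)
  args <- list(mat = unclass(mat), cluster_rows = tree, cluster_cols = tree,
               main = sprintf("Color distances (%s)", attr(mat, "metric") %||% ""),
               ...)
  if (!is.null(outfile)) args$filename <- outfile
  do.call(pheatmap::pheatmap, args)
  invisible(list(tree = tree, order = tree$order))
}

#' Scatter a pixel set in its color space
#'
#' Static 3D scatterplot of (optionally subsampled) pixels, each point drawn
#' in its own color. Axes are labeled with the active space's channel names
#' and span that space's default channel bounds.
#'
#' @param pixels a `pixel_set`.
#' @param outfile PNG path, or `NULL` to draw on the current device.
#' @param max_points display cap; larger sets are subsampled (seed recorded in
#'   the return value).
#' @param seed RNG seed for the subsample.
#' @param white illuminant used to render Lab coordinates as screen colors.
#' @return invisibly, a list with the number of points drawn and the seed.
#' @export
plot_pixels <- function(pixels, outfile = NULL, max_points = 50000L, seed = 1L,
                        white = "D65") {
  stopifnot(inherits(pixels, "pixel_set"))
  n <- nrow(pixels$coords)
  if (n < 1L) stop("nothing to plot: empty pixel set", call. = FALSE)
  shown <- sample_pixels(pixels, max_points, seed)
  coords <- shown$coords
  rgb <- switch(pixels$space,
                rgb = coords,
                hsv = hsv_to_rgb_matrix(coords),
                lab = pmin(pmax(lab_to_rgb_matrix(coords,
                                                  reference_white(white)), 0), 1))
  cols <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3])
  bounds <- default_channel_bounds(pixels$space)
  chs <- channel_names(pixels$space)
  df <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  p <- lattice::cloud(z ~ x * y, data = df, col = cols, pch = 16, cex = 0.4,
                      xlab = chs[1], ylab = chs[2], zlab = chs[3],
                      xlim = bounds[[1]], ylim = bounds[[2]], zlim = bounds[[3]])
  if (!is.null(outfile)) {
    grDevices::png(outfile, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  print(p)
  invisible(list(n_shown = nrow(coords), seed = seed))
}
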