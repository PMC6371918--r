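# Synthetic benchmark images: solid / two-color squares with exact pixel
# proportions, and green-screen scenes with planted ground truth. Every file
# is written as lossless 8-bit PNG so reloading recovers the stated colors and
# proportions with zero error.

# snap a 0-1 color to the 8-bit grid PNG will store
quantize8 <- function(color) round(color * 255) / 255

write_color_image <- function(path, colors_by_pixel, size) {
  # colors_by_pixel: (size^2) x 3 matrix in row-major scan order
  img <- array(0, dim = c(size, size, 3))
  for (ch in 1:3) {
    img[, , ch] <- matrix(colors_by_pixel[, ch], size, size, byrow = TRUE)
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Generate the color-quantity benchmark squares
#'
#' Five PNG squares, labeled A-E, mixing cyan (0,1,1) and red (1,0,0) in exact
#' proportions 1, 3/4, 1/2, 1/4, 0 cyan. Mixed squares use contiguous blocks;
#' every size/center/EMD computation in this package is invariant to pixel
#' layout, so the layout is presentational only. Normalized RGB earth mover's
#' distances between these squares equal the absolute difference of their cyan
#' proportions -- a linear yardstick for the metric.
#'
#' @param outdir directory to write into (created if needed).
#' @param size side length in pixels; must be divisible by 4 so quarters are
#'   exact (default 100).
#' @return named character vector of the five file paths (`A` ... `E`).
#' @export
generate_quantity_set <- function(outdir, size = 100L) {
  size <- as.integer(size)
  if (size %% 4L != 0L) stop("`size` must be divisible by 4", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cyan <- c(0, 1, 1); red <- c(1, 0, 0)
  props <- c(A = 1, B = 0.75, C = 0.5, D = 0.25, E = 0)
  paths <- character(0)
  for (nm in names(props)) {
    n_cyan <- as.integer(round(props[[nm]] * size^2))
    px <- rbind(matrix(rep(cyan, n_cyan), ncol = 3, byrow = TRUE),
                matrix(rep(red, size^2 - n_cyan), ncol = 3, byrow = TRUE))
    paths[nm] <- file.path(outdir, paste0(nm, ".png"))
    write_color_image(paths[nm], px, size)
  }
  paths
}

#' Generate solid squares along the blue-yellow gradient
#'
#' Squares from pure blue (0,0,1) to pure yellow (1,1,0). Endpoints are exact;
#' any intermediate squares are linear RGB interpolants snapped to the 8-bit
#' grid. (Linear interpolation is this package's choice of gradient; it is a
#' convenient, reproducible ramp, not a reconstruction of any particular
#' published figure's intermediate colors.)
#'
#' @param outdir directory to write into.
#' @param size side length in pixels (default 100).
#' @param steps number of squares, >= 2 (default 2: just the endpoints).
#' @return named character vector of file paths (`F`, `G`, ...).
#' @export
generate_similarity_endpoints <- function(outdir, size = 100L, steps = 2L) {
  steps <- as.integer(steps)
  if (steps < 2L) stop("`steps` must be at least 2", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t <- seq(0, 1, length.out = steps)
  nms <- LETTERS[seq(6L, 5L + steps)]
  paths <- character(0)
  for (i in seq_len(steps)) {
    col <- quantize8(c(t[i], t[i], 1 - t[i]))
    paths[nms[i]] <- file.path(outdir, paste0(nms[i], ".png"))
    write_color_image(paths[nms[i]], matrix(col, size^2, 3, byrow = TRUE), size)
  }
  paths
}

#' Specify a synthetic green-screen scene
#'
#' @param size side length in pixels.
#' @param patch_colors n x 3 matrix (or list of RGB triplets) of object patch
#'   colors on a 0-1 scale; snapped to the 8-bit grid.
#' @param proportions patch proportions of the *object* (not the whole image);
#'   must sum to 1.
#' @param background uniform background color (default bright green (0,1,0)).
#' @param layout `"blocks"` (contiguous runs) or `"stripes"` (interleaved
#'   rows); under a fixed `seed` the object pixels are additionally shuffled so
#'   patches are speckled rather than solid.
#' @param seed integer controlling the shuffle; `NULL` keeps the layout
#'   deterministic runs of pixels.
#' @return a `scene_spec` for [generate_greenscreen_scene()].
#' @export
scene_spec <- function(size = 100L, patch_colors, proportions,
                       background = c(0, 1, 0),
                       layout = c("blocks", "stripes"), seed = NULL) {
  layout <- match.arg(layout)
  if (is.list(patch_colors)) patch_colors <- do.call(rbind, patch_colors)
  patch_colors <- as.matrix(patch_colors)
  if (ncol(patch_colors) != 3L || nrow(patch_colors) != length(proportions)) {
    stop("`patch_colors` must be one RGB triplet per proportion", call. = FALSE)
  }
  if (any(patch_colors < 0) || any(patch_colors > 1) ||
      any(background < 0) || any(background > 1)) {
    stop("colors must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9 || any(proportions <= 0)) {
    stop("`proportions` must be positive and sum to 1", call. = FALSE)
  }
  structure(list(size = as.integer(size),
                 patch_colors = quantize8(patch_colors),
                 proportions = as.numeric(proportions),
                 background = quantize8(background),
                 layout = layout, seed = seed),
            class = "scene_spec")
}

#' Render a green-screen scene with planted ground truth
#'
#' Writes a PNG in which the object (the central half of the rows) realizes
#' the patch colors in exactly the specified pixel proportions (largest-
#' remainder rounding) on a uniform chroma-key background, plus a JSON sidecar
#' recording the quantized colors, exact realized proportions, and pixel
#' counts. Masking + binning the image must recover the sidecar exactly, which
#' is what makes these scenes useful for parameter-recovery tests; they make
#' no attempt at photorealism (no lighting, texture, or noise).
#'
#' @param spec a [scene_spec()].
#' @param outdir output directory.
#' @param name file stem (default `"scene"`).
#' @return list with `image` (PNG path), `truth` (JSON path), and the ground
#'   truth itself (`colors`, `proportions`, `counts`, `n_object_pixels`).
#' @details Errors if any patch color is within 0.1 of the background on every
#'   channel, since such a patch could not be separated by a chroma-key range.
#' @export
generate_greenscreen_scene <- function(spec, outdir, name = "scene") {
  stopifnot(inherits(spec, "scene_spec"))
  too_close <- apply(spec$patch_colors, 1, function(col) {
    max(abs(col - spec$background)) <= 0.1
  })
  if (any(too_close)) {
    stop("patch color(s) ", paste(which(too_close), collapse = ", "),
         " are within 0.1 of the background on every channel; ",
         "choose a more distinct background", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  size <- spec$size
  obj_rows <- seq.int(floor(size / 4) + 1L, floor(size / 4) + floor(size / 2))
  n_obj <- length(obj_rows) * size

  counts <- floor(spec$proportions * n_obj)
  rem <- n_obj - sum(counts)
  if (rem > 0) {  # largest remainder
    frac <- spec$proportions * n_obj - counts
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }

  patch_idx <- rep(seq_along(counts), counts)
  if (spec$layout == "stripes") {
    patch_idx <- patch_idx[order(seq_along(patch_idx) %% length(counts),
                                 seq_along(patch_idx))]
  }
  if (!is.null(spec$seed)) {
    patch_idx <- with_seed(spec$seed, sample(patch_idx))
  }

  px <- matrix(spec$background, size^2, 3, byrow = TRUE)
  obj_linear <- as.vector(vapply(obj_rows, function(r) (r - 1L) * size + 1:size,
                                 integer(size)))
  px[obj_linear, ] <- spec$patch_colors[patch_idx, ]

  image_path <- file.path(outdir, paste0(name, ".png"))
  write_color_image(image_path, px, size)

  truth <- list(colors = lapply(seq_len(nrow(spec$patch_colors)),
                                function(i) as.numeric(spec$patch_colors[i, ])),
                proportions = counts / n_obj, counts = counts,
                n_object_pixels = n_obj, background = spec$background,
                layout = spec$layout, seed = spec$seed, size = size)
  truth_path <- file.path(outdir, paste0(name, "_truth.json"))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  c(list(image = image_path, truth = truth_path), truth)
}
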