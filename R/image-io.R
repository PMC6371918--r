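#' Define an inclusive RGB background range for chroma-key masking
#'
#' A pixel is treated as background when, for every channel simultaneously,
#' `lower[i] <= value[i] <= upper[i]` (both ends inclusive). Several ranges can
#' be combined in a plain list; a pixel is masked if it falls inside any of
#' them.
#'
#' @param lower,upper RGB triplets on a 0-1 scale with `lower[i] <= upper[i]`.
#' @return An object of class `"background_range"`.
#' @examples
#' # the bright-green screen used throughout the examples: any pixel with
#' # 0 <= R <= 0.4, 0.6 <= G <= 1 and 0 <= B <= 0.4 is ignored
#' background_range(c(0, 0.6, 0), c(0.4, 1, 0.4))
#' @export
background_range <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L) {
    stop("`lower` and `upper` must be RGB triplets", call. = FALSE)
  }
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("background bounds must be finite", call. = FALSE)
  }
  if (any(lower < 0) || any(upper > 1)) {
    stop("background bounds must lie in [0, 1]", call. = FALSE)
  }
  if (any(lower > upper)) {
    stop("each lower bound must not exceed its upper bound", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper), class = "background_range")
}

#' @export
print.background_range <- function(x, ...) {
  cat(sprintf("Background range: R [%g, %g], G [%g, %g], B [%g, %g]\n",
              x$lower[1], x$upper[1], x$lower[2], x$upper[2],
              x$lower[3], x$upper[3]))
  invisible(x)
}

as_background_ranges <- function(background) {
  if (is.null(background)) return(list())
  if (inherits(background, "background_range")) return(list(background))
  if (is.list(background) &&
      all(vapply(background, inherits, logical(1), "background_range"))) {
    return(background)
  }
  stop("`background` must be a background_range or a list of them", call. = FALSE)
}

# Construct a pixel_set: an N x 3 coordinate matrix in a declared color space.
pixel_set <- function(coords, space = c("rgb", "hsv", "lab"),
                      n_source_pixels = nrow(coords), source = NA_character_) {
  space <- match.arg(space)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("pixel coordinates must have 3 columns", call. = FALSE)
  storage.mode(coords) <- "double"
  colnames(coords) <- channel_names(space)
  structure(list(coords = coords, space = space,
                 n_source_pixels = as.integer(n_source_pixels),
                 source = source),
            class = "pixel_set")
}

channel_names <- function(space) {
  switch(space,
         rgb = c("R", "G", "B"),
         hsv = c("H", "S", "V"),
         lab = c("L", "a", "b"),
         stop("unknown color space: ", space, call. = FALSE))
}

#' @export
print.pixel_set <- function(x, ...) {
  cat(sprintf("<pixel_set> %d pixels in %s space (of %d object pixels)\n",
              nrow(x$coords), toupper(x$space), x$n_source_pixels))
  if (!is.na(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @export
as.data.frame.pixel_set <- function(x, ...) as.data.frame(x$coords)

#' Read an image and split object pixels from a chroma-key background
#'
#' Reads a PNG or JPEG into a height x width x 3 array on a 0-1 scale (8- and
#' 16-bit integer channels are divided by their type maximum) and returns,
#' alongside it, the flattened set of pixels that do **not** fall inside the
#' background color range(s). Fully transparent PNG pixels (alpha = 0) are
#' treated as background regardless of color; partially transparent pixels are
#' composited over white before masking.
#'
#' @param path path to a PNG or JPEG file.
#' @param background a [background_range()], a list of them, or `NULL` to keep
#'   every pixel.
#' @return A list of class `"color_image"` with elements `img` (the 0-1 RGB
#'   array), `pixels` (a `pixel_set` of non-background pixels in row-major scan
#'   order), and `path`.
#' @details Grayscale and CMYK files are rejected with a format error; use an
#'   image editor to export 3-channel RGB first. If *every* pixel matches the
#'   background range the function stops with an "empty object" error, because
#'   binning an empty pixel set is undefined. JPEG chroma subsampling can
#'   scatter off-key pixels along mask borders; lossless PNG masks are
#'   recommended.
#' @seealso [mask_background()], [background_range()]
#' @export
load_image <- function(path, background = background_range(c(0, 0.6, 0),
                                                           c(0.4, 1, 0.4))) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           stop("unsupported extension '", ext, "'")),
    error = function(e) {
      stop("cannot read image '", path, "': ", conditionMessage(e), call. = FALSE)
    })

  alpha_zero <- NULL
  if (length(dim(raw)) != 3L || dim(raw)[3] < 3L) {
    stop("image '", path, "' is not 3-channel RGB (grayscale or indexed ",
         "files must be promoted to RGB before loading)", call. = FALSE)
  }
  if (dim(raw)[3] > 4L) {
    stop("image '", path, "' has ", dim(raw)[3],
         " channels; only RGB(A) is supported (is it CMYK?)", call. = FALSE)
  }
  img <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 4L) {
    a <- raw[, , 4]
    alpha_zero <- a == 0
    for (ch in 1:3) {  # composite partial alpha over white
      img[, , ch] <- img[, , ch] * a + (1 - a)
    }
  }

  pixels <- mask_background(img, background, drop = alpha_zero, source = path)
  if (nrow(pixels$coords) == 0L) {
    stop("empty object: every pixel of '", path,
         "' matches the background range", call. = FALSE)
  }
  structure(list(img = img, pixels = pixels, path = path), class = "color_image")
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x$img)
  cat(sprintf("<color_image> %d x %d px, %d object pixels  (%s)\n",
              d[1], d[2], nrow(x$pixels$coords), x$path))
  invisible(x)
}

#' Mask background pixels out of an RGB image array
#'
#' A pixel is excluded iff it lies inside one of the background ranges on all
#' three channels simultaneously (inclusive at both ends). Kept and masked
#' counts always sum to `height * width`.
#'
#' @param image a height x width x 3 array with values in 0-1.
#' @param background a [background_range()], list of them, or `NULL`.
#' @param drop optional logical matrix of pixels to discard unconditionally
#'   (used internally for fully transparent PNG pixels).
#' @param source path recorded in the result, for provenance.
#' @return A `pixel_set` in RGB space; `n_source_pixels` is the number of kept
#'   pixels. An empty result is allowed here (unlike [load_image()]).
#' @export
mask_background <- function(image, background = NULL, drop = NULL,
                            source = NA_character_) {
  if (inherits(image, "color_image")) image <- image$img
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) {
    stop("`image` must be a height x width x 3 array", call. = FALSE)
  }
  npx <- d[1] * d[2]
  # row-major scan order: row 1 left-to-right, then row 2, ...
  ord <- as.vector(t(matrix(seq_len(npx), d[1], d[2])))
  coords <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                  as.vector(image[, , 3]))[ord, , drop = FALSE]

  masked <- rep(FALSE, npx)
  for (rng in as_background_ranges(background)) {
    inside <- coords[, 1] >= rng$lower[1] & coords[, 1] <= rng$upper[1] &
              coords[, 2] >= rng$lower[2] & coords[, 2] <= rng$upper[2] &
              coords[, 3] >= rng$lower[3] & coords[, 3] <= rng$upper[3]
    masked <- masked | inside
  }
  if (!is.null(drop)) masked <- masked | as.vector(drop)[ord]

  kept <- coords[!masked, , drop = FALSE]
  pixel_set(kept, space = "rgb", n_source_pixels = nrow(kept), source = source)
}

#' Write a pixel set to a headered CSV
#'
#' Columns are the channel names of the active color space (R,G,B / H,S,V /
#' L,a,b). Values are written at full double precision.
#'
#' @param pixels a `pixel_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pixels <- function(pixels, path) {
  stopifnot(inherits(pixels, "pixel_set"))
  df <- as.data.frame(format(pixels$coords, digits = 17, trim = TRUE,
                             scientific = FALSE))
  names(df) <- colnames(pixels$coords)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
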