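# Color space conversions: sRGB <-> CIE Lab (with standard illuminants) and
# RGB <-> HSV. All conversions are elementwise, double precision, no lookup
# tables.

# CIE 1931 2-degree observer tristimulus values, Y normalized to 1.
REF_WHITES <- list(
  A   = c(1.09850, 1, 0.35585),
  B   = c(0.99072, 1, 0.85223),
  C   = c(0.98074, 1, 1.18232),
  E   = c(1.00000, 1, 1.00000),
  D50 = c(0.96422, 1, 0.82521),
  D55 = c(0.95682, 1, 0.92149),
  D65 = c(0.95047, 1, 1.08883),
  D75 = c(0.94972, 1, 1.22638)
)

# sRGB primaries (IEC 61966-2-1), linear RGB -> XYZ under D65. Columns are
# rescaled so that RGB (1,1,1) maps to the D65 white exactly (the standard
# derivation normalizes the primaries to the white point; the re-scaling is
# below 1e-6 and guarantees white -> L = 100, grays -> a = b = 0).
SRGB_TO_XYZ <- local({
  m <- matrix(c(
    0.4124564, 0.3575761, 0.1804375,
    0.2126729, 0.7151522, 0.0721750,
    0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  m %*% diag(solve(m, REF_WHITES[["D65"]]))
})

BRADFORD <- matrix(c(
   0.8951,  0.2664, -0.1614,
  -0.7502,  1.7135,  0.0367,
   0.0389, -0.0685,  1.0296), 3, 3, byrow = TRUE)

#' Look up a standard illuminant's reference white
#'
#' @param name one of `"A"`, `"B"`, `"C"`, `"E"`, `"D50"`, `"D55"`, `"D65"`,
#'   `"D75"`. D65 (indirect daylight) is the usual choice for photographs.
#' @return list with `name` and `xyz` (tristimulus triplet, Y = 1).
#' @export
reference_white <- function(name = "D65") {
  if (inherits(name, "reference_white")) return(name)
  if (!is.character(name) || length(name) != 1L || !name %in% names(REF_WHITES)) {
    stop("unknown reference white '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(REF_WHITES), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, xyz = REF_WHITES[[name]]),
            class = "reference_white")
}

# Bradford chromatic adaptation matrix taking XYZ under `from` to XYZ under `to`.
adaptation_matrix <- function(from_xyz, to_xyz) {
  cone_from <- as.vector(BRADFORD %*% from_xyz)
  cone_to <- as.vector(BRADFORD %*% to_xyz)
  solve(BRADFORD) %*% diag(cone_to / cone_from) %*% BRADFORD
}

# sRGB inverse companding: nonlinear 0-1 values -> linear-light RGB.
srgb_decompand <- function(x) {
  ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
}

srgb_compand <- function(x) {
  ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

lab_f <- function(t) {
  delta3 <- (6 / 29)^3
  ifelse(t > delta3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

lab_f_inv <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta, t^3, 3 * delta^2 * (t - 4 / 29))
}

rgb_to_lab_matrix <- function(coords, white) {
  linear <- srgb_decompand(coords)
  xyz <- linear %*% t(SRGB_TO_XYZ)
  if (white$name != "D65") {
    xyz <- xyz %*% t(adaptation_matrix(REF_WHITES[["D65"]], white$xyz))
  }
  fx <- lab_f(xyz[, 1] / white$xyz[1])
  fy <- lab_f(xyz[, 2] / white$xyz[2])
  fz <- lab_f(xyz[, 3] / white$xyz[3])
  cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
}

lab_to_rgb_matrix <- function(coords, white) {
  fy <- (coords[, 1] + 16) / 116
  fx <- fy + coords[, 2] / 500
  fz <- fy - coords[, 3] / 200
  xyz <- cbind(lab_f_inv(fx) * white$xyz[1],
               lab_f_inv(fy) * white$xyz[2],
               lab_f_inv(fz) * white$xyz[3])
  if (white$name != "D65") {
    xyz <- xyz %*% t(adaptation_matrix(white$xyz, REF_WHITES[["D65"]]))
  }
  linear <- xyz %*% t(solve(SRGB_TO_XYZ))
  srgb_compand(linear)
}

#' Convert RGB pixels to CIE L*a*b*
#'
#' Pixels are assumed to be sRGB-encoded (the de facto standard for PNG/JPEG):
#' the piecewise sRGB inverse companding is applied, linear RGB is mapped to
#' XYZ with the sRGB primaries, and the CIE piecewise cube-root transform
#' yields L (0-100), a (red-green) and b (blue-yellow). Non-D65 illuminants
#' are reached by Bradford chromatic adaptation. In-gamut RGB input always
#' lands with a and b inside [-128, 127].
#'
#' @param pixels a `pixel_set` in RGB space (values in 0-1).
#' @param white illuminant name or [reference_white()]; default `"D65"`.
#' @return a `pixel_set` in Lab space.
#' @export
rgb_to_lab <- function(pixels, white = "D65") {
  stopifnot(inherits(pixels, "pixel_set"))
  if (pixels$space != "rgb") stop("`pixels` must be in RGB space", call. = FALSE)
  white <- reference_white(white)
  out <- pixel_set(rgb_to_lab_matrix(pixels$coords, white), space = "lab",
                   n_source_pixels = pixels$n_source_pixels,
                   source = pixels$source)
  attr(out, "ref_white") <- white$name
  out
}

#' Convert CIE L*a*b* pixels back to sRGB
#'
#' Exact inverse of [rgb_to_lab()] on the sRGB gamut interior. Out-of-gamut
#' colors are clipped to [0, 1]; the number of clipped pixels is reported via
#' a warning and recorded in the `"clipped"` attribute.
#'
#' @inheritParams rgb_to_lab
#' @return a `pixel_set` in RGB space.
#' @export
lab_to_rgb <- function(pixels, white = "D65") {
  stopifnot(inherits(pixels, "pixel_set"))
  if (pixels$space != "lab") stop("`pixels` must be in Lab space", call. = FALSE)
  white <- reference_white(white)
  rgb <- lab_to_rgb_matrix(pixels$coords, white)
  clipped <- sum(rowSums(rgb < -1e-9 | rgb > 1 + 1e-9) > 0)
  if (clipped > 0) {
    warning(clipped, " out-of-gamut pixel(s) clipped to [0, 1]", call. = FALSE)
  }
  rgb <- pmin(pmax(rgb, 0), 1)
  out <- pixel_set(rgb, space = "rgb",
                   n_source_pixels = pixels$n_source_pixels,
                   source = pixels$source)
  attr(out, "clipped") <- clipped
  out
}

#' Convert RGB pixels to HSV
#'
#' Standard hexcone model; all three channels are returned on a 0-1 scale
#' (hue = angle / 360 degrees; achromatic pixels get hue 0).
#'
#' @param pixels a `pixel_set` in RGB space.
#' @return a `pixel_set` in HSV space.
#' @export
rgb_to_hsv <- function(pixels) {
  stopifnot(inherits(pixels, "pixel_set"))
  if (pixels$space != "rgb") stop("`pixels` must be in RGB space", call. = FALSE)
  hsv <- t(grDevices::rgb2hsv(t(pixels$coords), maxColorValue = 1))
  pixel_set(hsv, space = "hsv", n_source_pixels = pixels$n_source_pixels,
            source = pixels$source)
}

# Hexcone HSV -> RGB (all channels 0-1); used for rendering pixel/bin colors.
hsv_to_rgb_matrix <- function(hsv) {
  h <- hsv[, 1] * 6; s <- hsv[, 2]; v <- hsv[, 3]
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Convert a pixel set to another color space
#'
#' Dispatcher over [rgb_to_lab()], [lab_to_rgb()] and [rgb_to_hsv()]; HSV is
#' reached from Lab (and vice versa) through RGB.
#'
#' @param pixels a `pixel_set`.
#' @param to target space: `"rgb"`, `"hsv"`, or `"lab"`.
#' @param white illuminant for any Lab leg of the conversion.
#' @return a `pixel_set` in the target space.
#' @export
convert_color_space <- function(pixels, to = c("rgb", "hsv", "lab"),
                                white = "D65") {
  to <- match.arg(to)
  stopifnot(inherits(pixels, "pixel_set"))
  if (pixels$space == to) return(pixels)
  if (pixels$space == "hsv") {
    pixels <- pixel_set(hsv_to_rgb_matrix(pixels$coords), space = "rgb",
                        n_source_pixels = pixels$n_source_pixels,
                        source = pixels$source)
    if (to == "rgb") return(pixels)
  }
  if (pixels$space == "lab") {
    pixels <- suppressWarnings(lab_to_rgb(pixels, white))
    if (to == "rgb") return(pixels)
  }
  switch(to,
         lab = rgb_to_lab(pixels, white),
         hsv = rgb_to_hsv(pixels),
         rgb = pixels)
}

#' Subsample a large pixel set before expensive conversions
#'
#' Lab conversion cost grows with pixel count; a uniform random sample of 1e5
#' pixels is an accurate stand-in for a whole photograph. Sets at or under the
#' cap are returned unchanged; larger sets are sampled without replacement,
#' reproducibly for a fixed seed.
#'
#' @param pixels a `pixel_set`.
#' @param limit maximum number of pixels to keep (default 100000).
#' @param seed RNG seed for the draw; recorded in the `"sample_seed"`
#'   attribute of the result.
#' @return a `pixel_set` with at most `limit` rows; downstream bin proportions
#'   are taken over the sample.
#' @export
sample_pixels <- function(pixels, limit = 1e5, seed = 1L) {
  stopifnot(inherits(pixels, "pixel_set"), limit >= 1)
  n <- nrow(pixels$coords)
  if (n <= limit) return(pixels)
  idx <- with_seed(seed, sample.int(n, limit))
  out <- pixel_set(pixels$coords[idx, , drop = FALSE], space = pixels$space,
                   n_source_pixels = length(idx),
                   source = pixels$source)
  attr(out, "sample_seed") <- seed
  out
}
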