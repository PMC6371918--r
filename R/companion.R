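#' Integration checks against the original example photographs
#'
#' Some published reference values -- the flower's printed 8-bin Lab histogram,
#' the butterfly mimicry heatmaps, and the flounder camouflage scores (fish vs
#' substrate 3.05; substrate vs substrate 9.39) -- depend on photographs
#' distributed in the original package's companion repository, not on anything
#' this package can synthesize. When given a local copy of those photographs,
#' this helper reruns the documented parameter sets and returns the computed
#' objects so they can be compared with the published figures by eye; it is an
#' optional integration check, not part of the automated test suite.
#'
#' @param dir directory containing the companion photographs, laid out as in
#'   the original examples repository (`Flower/`, `Butterfly_mimicry/`,
#'   `Flounder_camouflage/`).
#' @return a list with whichever of `flower_histogram` (2x2x2 Lab histogram,
#'   a/b bounds +-100, D65), `butterfly_matrices` (k = 3 k-means, Lab/D65,
#'   EMD and chi-squared matrices), and `flounder_matrix` (2x3x5 Lab histogram,
#'   a in [-20, 40], b in [0, 50], EMD) could be computed from the files
#'   present.
#' @export
check_companion_examples <- function(dir) {
  if (!is.character(dir) || length(dir) != 1L || !dir.exists(dir)) {
    stop("companion photographs not available: directory '", dir,
         "' does not exist. These checks require the original example ",
         "photographs and are optional; all synthetic benchmarks run ",
         "without them.", call. = FALSE)
  }
  out <- list()
  flower <- list.files(file.path(dir, "Flower"), pattern = "\\.(png|jpe?g)$",
                       ignore.case = TRUE, full.names = TRUE)
  if (length(flower) >= 1L) {
    px <- load_image(flower[1],
                     background_range(c(0, 0.6, 0), c(0.4, 1, 0.4)))$pixels
    px <- rgb_to_lab(px, "D65")
    out$flower_histogram <- histogram_bin(
      px, bins = c(2, 2, 2),
      channel_bounds = list(c(0, 100), c(-100, 100), c(-100, 100)),
      label = "flower")
  }
  bdir <- file.path(dir, "Butterfly_mimicry")
  if (dir.exists(bdir)) {
    sets <- bin_image_set(bdir, method = "kmeans", color_space = "lab",
                          white = "D65", k = 3L,
                          background = background_range(c(0.8, 0.8, 0.8),
                                                        c(1, 1, 1)))
    sets <- order_clusters(sets)
    out$butterfly_matrices <- list(
      emd = distance_matrix(sets, "emd", normalize = FALSE),
      chisq = distance_matrix(sets, "chisq"))
  }
  fdir <- file.path(dir, "Flounder_camouflage")
  if (dir.exists(fdir)) {
    sets <- bin_image_set(fdir, method = "hist", color_space = "lab",
                          white = "D65", bins = c(2, 3, 5),
                          channel_bounds = list(c(0, 100), c(-20, 40), c(0, 50)),
                          background = background_range(c(0, 0.4, 0),
                                                        c(0.6, 1, 0.6)))
    out$flounder_matrix <- distance_matrix(sets, "emd", normalize = FALSE)
  }
  if (!length(out)) {
    stop("companion photographs not available: no recognized subdirectories ",
         "under '", dir, "'", call. = FALSE)
  }
  out
}
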