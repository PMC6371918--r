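Package: chromadist
Title: Quantitative Color Profiling and Comparison of Digital Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts digital images of background-masked objects into
    multidimensional color profiles (fixed-boundary 3D histograms or k-means
    cluster sets) in RGB, HSV, or CIE Lab color space, and compares images
    pairwise with earth mover's distance (optimal transport), chi-squared
    distance, or center/size-weighted metrics to produce labeled color
    distance matrices. Includes chroma-key background masking, standard
    illuminant handling for Lab conversion, Hungarian-algorithm alignment of
    k-means clusters across images, synthetic benchmark image generators, and
    a one-command pipeline from an image directory to a clustered heatmap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    jpeg,
    clue,
    jsonlite,
    lattice,
    pheatmap,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    optparse,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
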