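# chromadist

Quantitative color profiling and comparison of digital images in R.

Biologists routinely need to compare the *colors* of organisms — mimicry rings
in butterflies, camouflage against a substrate, palettes across a clade of
reef fishes — from ordinary digital photographs, without spectrophotometry
and without subjective scoring. chromadist turns each background-masked
photograph into a **color profile**: its pixels are treated as points in a
3D color space (RGB, HSV, or CIE L\*a\*b\*), then reduced to a small set of
weighted clusters, either a fixed-boundary 3D histogram or a k-means palette.
Profiles are compared pairwise with the **earth mover's distance** (EMD, the
1-Wasserstein metric): writing a profile as mass `s_i` at color-space points
`c_i`, the distance between profiles *P* and *Q* is the optimal-transport cost

    EMD(P, Q) = min_f  Σ_ij  f_ij · ||c_i − q_j||      subject to
                Σ_j f_ij = s_i,   Σ_i f_ij = t_j,   f_ij ≥ 0,

so moving a lot of mass, or moving it far across color space, both raise the
score. Unlike bin-wise metrics (χ², also provided), EMD knows that orange is
close to red and far from teal. In RGB/HSV the maximum score is the unit-cube
diagonal √3 (all mass moved as far as possible), so normalized scores live in
[0, 1]; CIE Lab has no universal maximum and scores are left raw.

The end product of an analysis is a labeled, symmetric **color distance
matrix** for an image set, ready for clustering, ordination, or comparative
statistics.

## What's inside

* chroma-key masking: pixels inside user-given inclusive RGB range(s) —
  e.g. a bright-green screen — are excluded before any analysis
* strict sRGB → CIE Lab conversion with standard illuminants (A, B, C, E,
  D50–D75) and Bradford chromatic adaptation; HSV via the hexcone model
* histogram binning (half-open boxes, positionally comparable across images,
  restrictable channel bounds) and seeded k-means++ (exactly k clusters)
* Hungarian-algorithm alignment of k-means clusters across images, so like
  colors are compared with like
* four metrics: EMD (exact transportation LP, solved in-package), χ²,
  mean center distance, and a size/color weighted combination
* synthetic benchmark generators (two-color proportion squares, blue–yellow
  gradient squares, green-screen scenes with planted ground truth)
* a one-call pipeline writing the matrix CSV, per-image cluster CSVs, a
  clustered heatmap, and a full run-metadata record; plus a thin CLI
  (`inst/cli/chromadist`)

## Worked example

A synthetic green-screen scene with three planted patch colors covering 50%,
30%, and 20% of the object:

```r
library(chromadist)

spec <- scene_spec(size = 100,
                   patch_colors = rbind(c(0.85, 0.15, 0.10),   # red
                                        c(0.10, 0.15, 0.90),   # blue
                                        c(0.95, 0.90, 0.15)),  # yellow
                   proportions = c(0.5, 0.3, 0.2), seed = 19)
sc <- generate_greenscreen_scene(spec, tempdir(), name = "demo")

px <- load_image(sc$image, background_range(c(0, 0.8, 0), c(0.2, 1, 0.2)))$pixels
px
#> <pixel_set> 5000 pixels in RGB space (of 5000 object pixels)
#>   source: /tmp/.../demo.png

kmeans_bin(px, k = 3, seed = 2, label = "demo")
#> <color_clusters> kmeans, 3 bins, RGB space  [demo]
#>       R     G     B size count
#> 1 0.851 0.149 0.102  0.5  2500
#> 2 0.102 0.149 0.902  0.3  1500
#> 3 0.949 0.902 0.149  0.2  1000
```

The 10,000-pixel image masks down to the 5,000 object pixels, and k-means
recovers the three planted colors (to 8-bit quantization) and their
proportions exactly. The same pixels as a 2×2×2 CIE Lab histogram:

```r
histogram_bin(rgb_to_lab(px, "D65"), bins = c(2, 2, 2), label = "demo")
#> <color_clusters> hist, 8 bins, LAB space  [demo]
#>         L        a        b size count
#> 1 25.0000 -64.2500 -64.2500  0.0     0
#> 2 75.0000 -64.2500 -64.2500  0.0     0
#> 3 32.5180  63.4359 -93.3293  0.3  1500
#> ...
#> 7 47.2585  65.8594  51.8139  0.5  2500
#> 8 75.0000  63.2500  63.2500  0.0     0
```

Occupied bins sit at the mean color of their pixels; empty bins sit at their
box midpoints with size 0. And the classic quantity benchmark — five squares
mixing cyan (0,1,1) and red (1,0,0) in proportions 1, ¾, ½, ¼, 0 — through
the whole pipeline:

```r
d <- tempfile(); generate_quantity_set(d, size = 100)
image_cluster_pipeline(d, color_space = "rgb", method = "hist",
                       bins = c(3, 3, 3), metric = "emd", normalize = TRUE,
                       background_lower = NULL, background_upper = NULL,
                       out = "results_qty")
#> Color distance matrix (emd, normalized, RGB space), 5 images:
#>      A    B    C    D    E
#> A 0.00 0.25 0.50 0.75 1.00
#> B 0.25 0.00 0.25 0.50 0.75
#> C 0.50 0.25 0.00 0.25 0.50
#> D 0.75 0.50 0.25 0.00 0.25
#> E 1.00 0.75 0.50 0.25 0.00
```

Each normalized EMD equals the proportion of pixels that differ between two
squares — swapping ¼ of the image from cyan to red moves ¼ of the mass across
the full cube diagonal. `results_qty/` now holds the matrix CSV, per-image
cluster CSVs, a dendrogram-ordered heatmap, and `run_metadata.txt`.

The same run from a shell:

```sh
Rscript inst/cli/chromadist pipeline --input imgs/ --color-space lab \
    --ref-white D65 --method hist --bins 3,3,3 --metric emd \
    --lower 0,0.6,0 --upper 0.4,1,0.4 --seed 1 --out results/
```

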