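---
title: "Color profiling with earth mover's distance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color profiling with earth mover's distance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromadist)
```

chromadist measures how different two photographed objects are in color, by
amount and by kind, from nothing more than masked digital images. This
vignette is the package's own account of the method: the model, every
parameter that matters, the numerical conventions, and what the synthetic
benchmarks do and do not demonstrate.

## The model

An image is reduced to a *color profile*: a set of `k` clusters, each a point
`c_i` in a three-dimensional color space together with the proportion `s_i`
of object pixels it holds (`sum(s_i) = 1`). Two profiles are compared with
the earth mover's distance — the optimal-transport (1-Wasserstein) cost of
reshaping one profile's mass distribution into the other's, with Euclidean
distance between cluster centers as the per-unit transport cost. The
modelling assumptions are:

* **Spatial arrangement is ignored.** Profiles are bags of colored mass; two
  images with identical palettes in different spatial patterns are
  equidistant (distance 0). This is deliberate — the method targets palette
  similarity, and pattern analysis belongs to other tools.
* **The background is identified by color alone.** Masking assumes the
  photographer replaced the background with a uniform chroma-key color that
  no object pixel approaches.
* **Pixels are sRGB.** Files are assumed sRGB-encoded (the de facto PNG/JPEG
  standard); no white-balance or radiometric calibration is attempted, so
  images should be calibrated upstream.

## Color spaces

RGB is the computational workhorse: every channel lives in [0, 1], so the
EMD has the absolute maximum √3 (all mass moved along the unit-cube
diagonal) and scores normalize to [0, 1]. CIE L\*a\*b\* is approximately
perceptually uniform for *human* vision — equal distances mean roughly equal
perceived difference — at the cost of needing a reference white and having no
universal score maximum (the gamut of RGB-derived colors in Lab is an
irregular solid; `distance_matrix()` therefore refuses to normalize Lab EMDs
and warns). HSV is provided for segmentation-style uses; it makes no
perceptual claims.

The Lab transform is the strict sRGB standard: piecewise inverse companding
(linear segment below 0.04045, exponent 2.4 above), the IEC 61966-2-1
primaries matrix to XYZ, then the CIE piecewise cube-root transform
(`f(t) = t^{1/3}` above `(6/29)^3`, linear below). The primaries matrix is
column-rescaled (a sub-1e-6 adjustment) so that RGB white maps *exactly* to
the reference white — hence white → (100, 0, 0) and grays → `a = b = 0` to
machine precision, which the tests assert. Non-D65 illuminants are reached by
Bradford chromatic adaptation. These constants are stated because published
Lab values from other software differ at the ±1 level depending on the
conversion constants chosen; the package's own Table of benchmark distances
is asserted in tests to within one Lab unit for exactly this reason, with the
strict-sRGB value treated as ground truth. Conversion is elementwise double
precision; no lookup tables.

Lab conversion is the most expensive step, so `bin_image_set()` and the
pipeline subsample very large pixel sets before converting
(`sample_limit = 1e5` pixels by default, drawn uniformly without replacement
under the run's seed, which is recorded in the run metadata). A 100k-pixel
uniform sample is an accurate stand-in for whole-image bin proportions at the
bin sizes used here.

## Binning

**Histogram method (default).** Each channel's range is divided into
`bins[i]` equal intervals — half-open `[low, high)`, top interval closed —
so bin assignment is a true partition; a pixel on an interior boundary
belongs to the upper bin. Bins are emitted with the first channel's index
varying fastest, giving every image the same positional bin semantics. An
occupied bin's center is the mean of its member pixels (so centers track the
actual colors, not the grid); an empty bin sits at its box's geometric
midpoint with size 0. Default bounds are 0–1 for RGB/HSV and L 0–100,
a/b −128–127 for Lab — the range RGB-derived colors occupy in practice.
Restricting `a_bounds`/`b_bounds` to the range actually present in an image
set concentrates bins where the data are; pixels outside the declared bounds
are a hard error naming the channel and observed range, never a silent clamp,
because user-restricted bounds are a contract that the data are enclosed.

**k-means method.** Lloyd's algorithm with k-means++ seeding, 10 restarts by
default, best within-cluster sum of squares wins, deterministic under the
given seed. A center that loses all its members is re-seeded at the pixel
farthest from its current center, so the promised `k` clusters always come
back. k-means is the right choice when images share a known number of color
classes; the histogram is faster, unbiased by color proportions, and
positionally comparable, but can split one color across a boundary.

**Alignment.** k-means clusters come out unordered, so `order_clusters()`
permutes every set's bins by the minimum-total-center-distance bijection to a
reference set, solved with the Hungarian algorithm (`clue::solve_LSAP`),
verified in tests against exhaustive permutation search. Design choices made
here: the reference is the set with the lexicographically smallest label
(deterministic under sorted loading); assignment cost uses center positions
only, since trading off size against color is the business of the weighted
*metrics*, not of the matching; and equal-cost ties resolve to the lowest
lexicographic permutation (enforced for k ≤ 8; beyond that the solver's
deterministic output stands). `combine_cluster_sets()` averages aligned
profiles — sizes as plain means (each image weighs equally), centers as
pixel-count-weighted means (switch to `"equal"` to weigh images equally), and
the empty-bin midpoint rule re-applied afterwards.

## Distances

* **EMD** (default): the balanced transportation LP over the nonempty bins,
  solved exactly in-package by successive shortest augmenting paths with node
  potentials. Zero-size bins carry no mass and are dropped from the LP to
  keep it nondegenerate. Profiles are normalized to total mass 1 before
  solving; genuinely unbalanced inputs are rejected rather than partially
  matched.
* **χ²**: `sum((s_a − s_b)^2 / (s_a + s_b))` over positionally matched bins,
  zero-denominator terms contributing 0, no ½ prefactor (the convention is
  fixed here by documentation and tests). Blind to center positions: an
  all-black and an all-gray image can score as identical if their pixels land
  in the same boxes — the standard argument for preferring EMD.
* **color**: mean Euclidean distance between matched centers, sizes ignored.
* **weighted**: per matched pair,
  `color_weight·‖Δcenter‖ + size_weight·|Δsize|`, averaged over bins; weights
  must sum to 1.

Matrices are stored at full double precision; any rounding is display-only.

## Numerical conventions

* Transport solver tolerances: marginals are honored to 1e-8 (tested);
  supply/demand totals may differ by a relative 1e-6 before rejection
  (demand is rescaled to balance exactly); flows below 1e-12 of the total
  mass are snapped to zero. Ground distances are computed difference-first so
  coincident centers cost exactly 0 and `emd(x, x) == 0` holds identically.
* The solver is exact for nonnegative costs; the test suite checks it on 200
  random instances against an independent linear-program solution
  (scipy's HiGHS, via the `lp_oracle.py` helper) to 1e-6, plus a closed-form
  one-dimensional Wasserstein oracle in pure R and the metric axioms.
* Mixture linearity — for point masses A, B and the blend
  `M_t = {A: 1−t, B: t}`, `EMD(A, M_t) = t·EMD(A, B)` — is asserted to 1e-9;
  it is the structural law that makes the two-color benchmark squares a
  linear yardstick.
* k-means ties in assignment go to the lowest cluster index; restarts and
  seeding consume the RNG only inside a seed-scoped block, so library calls
  never perturb the caller's RNG state.
* Degenerate inputs: empty pixel sets cannot be binned; an image whose every
  pixel matches the background range raises an "empty object" error at load
  time; `k` above the number of distinct colors is an error advising a
  smaller `k`.
* Masking is evaluated on the 0–1 float scale after integer channels are
  divided by their type maximum (255 or 65535); bounds are inclusive on both
  ends, and a pixel must be inside on all three channels simultaneously to be
  masked. Fully transparent PNG pixels are background regardless of color;
  partial alpha is composited over white before masking (file formats do not
  define chroma-key semantics for alpha, so this is the package's
  convention).

## The synthetic benchmarks

`generate_quantity_set()` writes five squares mixing cyan (0,1,1) and red
(1,0,0) at exact pixel proportions 1, ¾, ½, ¼, 0 — by mixture linearity the
normalized RGB EMD between any two must equal the difference of their cyan
proportions, which the acceptance tests assert to 1e-6 on 100×100-pixel
squares (10,000 pixels each; the property is resolution-independent, and the
test suite uses 40×40 where only plumbing is being exercised).
`generate_similarity_endpoints()` writes solid squares from blue (0,0,1) to
yellow (1,1,0); the endpoints span the cube diagonal, so their normalized EMD
must be 1. Intermediates are linear RGB interpolants — a reproducible ramp,
chosen here as this package's gradient convention. All benchmark files are
lossless 8-bit PNG, not JPEG, so compression artifacts cannot blur exact
expectations.

`generate_greenscreen_scene()` plants patch colors at exact proportions
(largest-remainder rounding) on a uniform chroma-key background and writes a
JSON ground-truth sidecar; masking + k-means must recover the proportions
exactly and the centers to within 8-bit quantization, which is the
parameter-recovery test. The scenes emulate ideal masked photographs:
uniform patches, no lighting gradients, no texture, no JPEG chroma bleed, no
mask-boundary mixing. Passing these tests therefore demonstrates the
*machinery* — masking, conversion, binning, transport — is correct, not that
any particular field image is well-masked or well-calibrated. With real
JPEGs, chroma subsampling scatters off-key pixels along mask borders; no
de-speckling is applied, and lossless PNG masks are the recommended format.

Three published reference cases — a flower's printed 8-bin Lab histogram,
butterfly-mimicry heatmaps, and flounder-camouflage scores — depend on
photographs distributed with the original analyses that this package cannot
synthesize. `check_companion_examples()` reruns the documented parameter sets
when pointed at a local copy of those photographs and fails informatively
otherwise; those values are documented, not asserted.

## Pipeline and reporting

`image_cluster_pipeline()` validates the whole configuration before touching
any file, then runs load → convert → bin → align → distance matrix, and (when
`out` is given) writes the matrix CSV, per-image cluster CSVs (the package's
interchange format; doubles at full precision, bit-exact on reload), a
heatmap ordered by hierarchical clustering of the matrix (complete linkage by
default, configurable; the clustering is a visual aid, not a formal
grouping — the run metadata repeats this caveat), and a run-metadata record
with every parameter and seed. A fixed configuration and seed give
byte-identical matrix CSVs across runs, and the pipeline equals the
hand-composed module calls — both are tested. On failure the run's partial
outputs are removed.

## Known limitations

* Three channels only; ultraviolet or other extra channels are out of scope.
* No animal-vision cone-catch modeling — CIE Lab is uniform for human vision;
  calibrate upstream for other visual systems.
* No spatial/pattern information, by design.
* No automatic choice of `k` or of bin counts.
* Exact transport scales comfortably to the hundreds of bins used here; it is
  not an entropic/approximate solver for thousands of bins.
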