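---
title: "Dominant-color and edge-histogram retrieval: models and design choices"
author: "tongueCBIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-color and edge-histogram retrieval: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tongueCBIR)
```

# The problem

Clinical tongue inspection classifies tongues by color (pink, pale, purple,
purple-red, yellow-coated, white-coated, ...) and by surface texture
(fissures, teeth prints, coating thickness, exfoliation). Content-based
retrieval replaces manual annotation of a tongue-image archive with ranking
by feature similarity to a query image. This package implements such a
retrieval pipeline around two compact descriptors — a dominant-color
signature and a multi-scale edge histogram — and a normalized, weighted
fusion of their distances.

# Dominant-color extraction

## Color representation

Retrieval operates in HSV, where tongue classes order monotonically along
hue, saturation and value; RGB separates them poorly. `rgbToHsv()` is the
standard hexcone conversion (`V = max`, `S = (V - min)/V`, hue sextant from
the ordering of the channels). Two removable singularities are defined
away: `S = 0` when `V = 0`, and `H = 0` for achromatic pixels (`V = min`).

A coarse quantizer (`quantizeHsv()`) partitions HSV into nine regions —
black, gray, white, and six hue bands (red, yellow, green, cyan, blue,
purple). Two conventions make the map total and deterministic:

* hue intervals are half-open `[lo, hi)`, so a pixel at exactly 20 degrees
  is yellow, not red;
* the gray band covers `0.2 < v <= 0.9` for `s <= 0.1`. The classical
  region table leaves `0.8 < v <= 0.9` unassigned between gray and white;
  extending gray is the minimal change that keeps the map monotone in `v`.

## Palette initialization and GLA refinement

Random initialization of a color quantizer is unreliable on tongue images,
whose color modes are close together. `initialPalette()` therefore seeds
the clustering from the data: every coarse region holding more than a
fraction `areaThreshold` (default 0.15) of the pixels contributes one
initial center, the circular-mean color of its pixels. If no region
passes, the single largest region is used. The region count *is* the
initial number of main colors.

`extractMainColors()` then runs a generalized Lloyd (LBG) refinement:

1. **Assign** every pixel to the nearest center under the weighted squared
   HSV distance `w_h dh^2 + w_s ds^2 + w_v dv^2`, with hue normalized to
   `[0, 1)` and differenced circularly. The weights default to
   `(2, 1, 1)`: hue carries the class separation, so it is emphasized.
   Ties go to the lowest center index; empty clusters are dropped.
2. **Update** each center to the mean of its members (circular mean on
   hue), and repeat to convergence (center movement below `tol = 1e-6`
   in normalized units, at most `maxIter = 100` iterations).
3. **Split** any cluster whose within-cluster weighted mean squared error
   exceeds `splitThreshold` (default 0.01) into two centers offset by plus
   and minus half the member standard deviation along the coordinate of
   largest weighted variance — the standard LBG split. The split criterion
   is a scalar error, so the displacement direction is a design choice;
   the maximum-variance coordinate is the one the error actually lives in.
4. **Merge** center pairs closer than `mergeThreshold` (default 0.1) into
   their count-weighted mean, closest pair first.
5. Re-converge after each pass and stop when neither pass fires, capped at
   `maxRounds = 10` outer rounds to guarantee termination even if a split
   and a merge oscillate.

The split and merge thresholds are genuine tuning knobs with no canonical
values; the defaults are set so that palettes separated by much more than
the merge radius, with noise far below the split radius, are recovered
exactly — the regime the synthetic generator produces (see below). The
output is the descriptor `F = {(c_i, mu_i)}`, each main color with the
fraction of pixels it covers; fractions sum to 1 by construction because
every pixel is assigned.

`traditionalMainColors()` implements the classical baseline for
comparison: quantize every pixel to the nine regions, keep regions
covering at least 5% of the image, renormalize.

## Descriptor distance

The distance between two dominant-color descriptors is the quadratic
matching form

```
D^2 = sum_i mu1_i^2 + sum_j mu2_j^2 - 2 sum_ij a_ij mu1_i mu2_j,
a_ij = 1 - min(dist(c1_i, c2_j) / dmax, 1),
```

with `dist` the weighted circular-hue HSV distance. `dmax` is the radius
beyond which two colors count as fully dissimilar; the default 0.1
(weighted normalized units, about 25 degrees of pure hue difference)
matches the scale of the coarse quantizer's hue bands. Two caveats are
worth knowing. First, the similarity matrix `a` is not positive
semidefinite in general, so `D^2` can come out slightly negative for very
similar palettes; it is clamped at zero, which makes the distance a
premetric (`D = 0` does not strictly imply identity). Keeping `dmax`
small limits how often the clamp binds. Second, the form compares
descriptors of different lengths naturally, which a fixed-bin Euclidean
distance cannot; a 9-region-histogram Euclidean mode
(`method = "areahist"`) is available as the simpler alternative
interpretation.

# Edge-histogram extraction

Color alone cannot distinguish a fissured tongue from a smooth one of the
same shade. The texture descriptor summarizes edge structure at three
scales, extending the classical local-only edge histogram:

* **Local (80 bins).** The gray image (`g = 0.299 R + 0.587 G + 0.114 B`)
  is divided into a 4 x 4 grid of subimages; each subimage is tiled by 256
  blocks (a 16 x 16 grid; block sides are the largest even number fitting
  the subimage, trailing pixels dropped — evenness is required because
  each block is analyzed as four 2 x 2 macroblocks). The four macroblock
  mean grays are filtered by the five MPEG-7 edge operators — vertical
  `(1, -1, 1, -1)`, horizontal `(1, 1, -1, -1)`, 45-degree
  `(sqrt2, 0, 0, -sqrt2)`, 135-degree `(0, sqrt2, -sqrt2, 0)`,
  nondirectional `(2, -2, -2, 2)` — and the block takes the type of the
  largest absolute response if it strictly exceeds the edge threshold
  (default 20 gray levels), else no edge. Counts are normalized by the
  block count, so each of the 16 x 5 bins lies in `[0, 1]`.
* **Global (5 bins).** The mean of the local histogram over the 16
  subimages. The classical formulation is sometimes written as a plain
  sum; the mean is used here so that global bins live on the same `[0, 1]`
  scale as local bins, which the five-fold weight in the distance (below)
  then converts into the intended emphasis.
* **Semiglobal (65 bins).** Means over 13 subimage groups: the four
  columns of the grid, the four rows, the four corner 2 x 2 quadrants and
  the center 2 x 2 quadrant — the standard 13-group layout, which is the
  only grouping consistent with 13 x 5 = 65 bins.

An optional 3-bit encoding (`quantizeBins()`, uniform eight-level
quantizer with bin-center dequantization) compresses the 80 local bins for
storage; all distances are computed on the raw normalized bins, since
quantization is an encoding concern rather than a similarity one. The
gray conversion also accepts an alternative blue coefficient of 0.144
(`coeffs = "alt"`); those weights sum to 1.030, so the result is clipped —
the standard 0.114 is the default because it preserves luminance
normalization.

With the default 256 blocks per subimage the minimum image is 128 x 128;
smaller images are handled by lowering `blocksPerSubimage` (a perfect
square), e.g. 64 blocks for 64 x 64 images.

## Texture distance

```
D(Q, T) = sum |EH_q - EH_t|  +  5 sum |GH_q - GH_t|  +  sum |SGH_q - SGH_t|
```

an L1 distance over all 150 bins with the global bins weighted five-fold,
so the whole-image edge distribution counts as much as any localized
difference. This is a true metric (a weighted L1 sum). The plain 80-bin
L1 distance (`l1HistogramDistance()`) is retained as the classical
baseline.

# Fusion and retrieval

Raw color and texture distances are incommensurable, so each is mapped to
a similarity `s = (dmax - d)/dmax` in `[0, 1]` before fusion. The
normalizing maxima are the per-query empirical maxima over the indexed
collection: the farthest entry on each feature scores exactly 0 and an
identical entry scores exactly 1, with no invented constants. (Fixed
theoretical bounds would also satisfy the contract; per-query maxima were
chosen because they adapt to the collection and leave the ranking
invariant under any common rescaling of both maxima.) The fused score is
the convex combination `w1 s1 + w2 s2` with default weights 0.6 : 0.4
favoring color, the weighting that reflects color's stronger diagnostic
role; both weights are per-query configurable. Ties in the fused score
are broken lexicographically by image id for reproducibility.

Evaluation follows the usual retrieval conventions: with `L` returned
images, `M` of them relevant (same class label) and `D` relevant images in
the database, precision is `M/L` and recall `M/D`; `prCurve()` averages
both over a query set for every cutoff. Queries drawn from the index are
excluded from their own ranking during evaluation.

# The synthetic phantom generator

No tongue-image collection is bundled; `makePhantom()` renders the study
conditions synthetically, and all tests and the acceptance experiment run
on these phantoms.

A phantom is a flat-color image whose 1-3 palette colors occupy exact
pixel fractions, with an optional gray-level texture and Gaussian channel
noise. Stripe and diagonal textures are triangular waves rather than
square waves: a hard diagonal step sampled at macroblock resolution
produces corner configurations that the nondirectional filter scores
highest, whereas a linear ramp yields zero second difference and a clean
directional response — the triangular profile is what makes the planted
orientation the provable argmax. The checkerboard (cell size one pixel,
matching the macroblock of 2-pixel blocks) is the nondirectional texture;
`cracks` darkens random-walk polylines, mimicking fissures with mixed edge
orientations.

Three template sets define the default classes:

* `defaultColorTemplates()` — six two-color palettes whose dominant hues
  (270, 300, 335, 5, 30, 55 degrees) follow the hue ordering of the
  clinical color classes across the purple-red-yellow arc, separated by
  at least 25 degrees so that classes remain separable under the
  generator's +/-5 degree per-image hue jitter.
* `defaultTextureTemplates()` — five classes on one base color differing
  only in planted edge orientation.
* `defaultCombinedTemplates()` — six classes pairing three colors with
  three textures so that every color and every texture is shared by two
  classes: neither feature alone can separate the classes, which is the
  regime where fusion must help.

`makeFixtureDb()` renders seeded per-image variants (hue jitter, small
saturation/value jitter, resampled noise), each image from a seed derived
from the master seed, so collections are byte-reproducible.

What the phantoms deliberately do not model: illumination gradients and
camera color casts, specular highlights, tongue-shape variation and
segmentation error, and the soft, spatially correlated texture of real
papillae. Passing tests therefore demonstrate that the pipeline recovers
planted structure under controlled noise — not clinical performance.
Published precision figures from clinical archives cannot be reproduced
here; what the synthetic experiment reproduces is the qualitative
ordering (fused above either single feature).

# Numerical choices and degenerate inputs

* Circular means use the resultant-vector formula; a near-zero resultant
  (exactly opposed hues) falls back to the arithmetic mean for
  determinism.
* Lloyd convergence is center movement below `1e-6` normalized units; the
  per-phase objective trace is attached to every descriptor and is
  asserted nonincreasing in the tests.
* Assignment ties go to the lowest cluster index; empty clusters are
  dropped rather than reseeded.
* The edge threshold comparison is strict (`>`), and it applies to the
  absolute filter response.
* Images smaller than the block grid raise an error naming the remedy
  (`blocksPerSubimage`); blocks must be at least 2 x 2 with even sides.
* Uniform images yield one main color with fraction 1 and an all-zero
  edge histogram; both descriptors are well defined.
* If every indexed entry is equidistant from a query on one feature
  (zero maximum distance), that feature scores 1 for all entries rather
  than dividing by zero.

# Problem sizes

The test suite and the acceptance experiment use 48-64 pixel phantoms with
64 blocks per subimage for clustering and retrieval checks (20-replicate
recovery and fusion experiments; 10 databases of 30 images for the
acceptance run), and full 128 x 128 phantoms with the default 256-block
grid for descriptor-structure checks. These sizes exercise every code
path — grids, split/merge, fusion, evaluation — while each individual
extraction stays in the tens of milliseconds.

# A compact example

```{r example}
db <- makeFixtureDb(defaultCombinedTemplates(size = c(64, 64)),
                    nPerClass = 3, seed = 1)
idx <- buildIndex(db$images, db$labels,
                  ehdParams = EhdParams(blocksPerSubimage = 64))
rbind(color   = evaluateRetrieval(idx, topK = 2, w1 = 1,   w2 = 0),
      texture = evaluateRetrieval(idx, topK = 2, w1 = 0,   w2 = 1),
      fused   = evaluateRetrieval(idx, topK = 2, w1 = 0.6, w2 = 0.4))
```

# Known limitations

* The dominant-color distance is a premetric (see above); rankings are
  still well defined through the lexicographic tie-break.
* The split/merge thresholds are scale-coupled: images whose genuine color
  modes are closer than `mergeThreshold` collapse to one main color by
  design.
* The 3-bit encoding implements only the uniform quantizer; per-edge-type
  nonlinear code tables are not provided.
* Retrieval is exact exhaustive scan; no approximate indexing is
  attempted, which is appropriate for archive sizes in the hundreds to
  thousands.
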