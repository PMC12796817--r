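---
title: "Refining cell segmentation for spatial transcriptomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining cell segmentation for spatial transcriptomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrefine)
```

## The problem

Spatial transcriptomics assays such as Stereo-seq record gene expression at
sub-cellular spot resolution alongside a stained tissue image. Turning spots
into single-cell profiles requires segmenting every nucleus in the image, and
pre-trained segmentation models that work well on sparse, high-contrast
tissue routinely fail in dense, low-contrast regions — tightly packed
structures like the hippocampal pyramidal layers, where nuclei touch and
boundaries blur. The practical remedy is not training a new model but
*refining* an existing one on a small set of annotated patches drawn from
exactly the regions where it fails.

`segrefine` implements the computational scaffolding around that idea:

1. **patch preparation** — cropping annotation-sized patches from whole-slide
   images, padding them to a model's input size, converting binary
   (semantic) annotations to per-cell instance labels, and building grouped
   train/validation lists;
2. **instance-level evaluation** — IoU matching of predicted against
   ground-truth cells and the standard five metrics;
3. **morphometrics** — six summary statistics of cell arrangement, density,
   shape and boundary clarity;
4. **cell-bin expression** — mapping spot-level expression points into a
   segmentation mask and aggregating per-cell counts;
5. **a synthetic tissue generator** so all of the above is testable without
   microscope data; and
6. **the refinement loop** — an adapter contract for pluggable segmenters,
   driven round by round with an anti-forgetting restart rule.

The deep-learning backends themselves (Cellpose, StarDist, U-Net) are out of
scope: they are third-party training APIs. The package ships a classical
watershed baseline and a mock adapter so the loop logic is fully exercised.

## Instance evaluation

Predicted and ground-truth cells are matched one-to-one on
intersection-over-union of their pixel sets, at a threshold of 0.5 (the
conventional value; configurable). Matching is greedy in descending IoU with
ties broken by ascending label pair. For IoU strictly above 0.5 a cell can
overlap at most one partner that far, so the greedy result provably equals
the optimal assignment; the test suite confirms this against an exhaustive
maximum-bipartite-matching oracle on 200 random perturbed mask pairs.

From the match counts TP, FP, FN:

\[
\mathrm{Precision} = \frac{TP}{TP+FP},\quad
\mathrm{Recall} = \frac{TP}{TP+FN},\quad
F1 = \frac{2PR}{P+R},\quad
\mathrm{Jaccard} = \frac{TP}{TP+FP+FN},\quad
\mathrm{Dice} = \frac{2TP}{2TP+FP+FN}.
\]

At the instance level F1 and Dice are the same quantity and Jaccard equals
Dice/(2−Dice); both identities are verified exhaustively over the count grid
0..20³. Degenerate 0/0 cases are resolved by policy rather than left NaN:
two empty masks score 1.0 on all five metrics (nothing to find, nothing
found), and any other 0/0 ratio scores 0. This keeps batch aggregates
defined. Batch aggregation is the unweighted per-image mean (plus median and
sd); whether instances should instead be pooled across patches is genuinely
ambiguous in field practice, so the per-image convention is stated rather
than hidden.

## Morphometrics

Cells are extracted from the label image by connected-region analysis. Three
conventions matter:

* **Perimeter** is the count of pixel edges between a cell and any non-cell
  pixel (4-neighbourhood, image border included). This makes closed forms
  exact — an s×s square has perimeter 4s — at the cost of overestimating
  smooth boundaries relative to sub-pixel estimators. The choice favours
  testability; alternative estimators would scale all shape-complexity
  values but not their ordering.
* **Centroids** are means of 0-based pixel coordinates, x = column,
  y = row, the same frame the expression tables use.
* **A_total** is the full image pixel count. No tissue-region masking is
  attempted, so density is cells per image pixel.

The six metrics:

| metric | definition | needs |
|---|---|---|
| mean distance | mean over cells of the nearest-neighbour centroid distance | N ≥ 2 |
| compactness | (mean distance)² / mean cell area | N ≥ 2 |
| density | N / A_total | N ≥ 1 |
| distribution | population CV of local densities 3/D₍ᵢ,₃₎, D₍ᵢ,₃₎ = sum of cell i's three smallest neighbour distances | N ≥ 4 |
| shape complexity | mean(P²) / mean(A) — the ratio of means, **not** the mean of ratios | N ≥ 1 |
| edge contrast | mean Sobel gradient on cell-edge pixels / mean Sobel gradient on background pixels | ≥ 1 cell, non-uniform background |

σ_local uses the population divisor (N), matching the coefficient-of-
variation convention and keeping the statistic deterministic in N. Metrics
whose minimum N is not met are reported as `NA` with an explicit textual
flag, never silently zero, so downstream tables cannot mistake "undefined"
for "uniform".

Edge contrast details: RGB images are collapsed to Rec. 601 luminance; the
3×3 Sobel kernels are applied with a 1-pixel mirrored border; edge pixels
are cell pixels with a 4-neighbour of a different label (background or
another cell); background pixels are label-0 pixels at city-block distance
greater than 2 from any cell. The 2-pixel exclusion ring is a documented
choice — without it the cells' own edge gradients bleed into the background
mean and compress the ratio. A perfectly uniform background has zero mean
gradient and the ratio is reported undefined rather than infinite.

On the distribution statistic: the printed formula for D₍ᵢ,ₖ₎ in the source
material re-uses the cell index as its summation index; this package reads
it as the sum of the k smallest neighbour distances of cell i, the only
interpretation that yields a per-cell local density.

## Patch preparation

Cropping tiles the slide at a configurable stride (overlap is allowed by
setting stride < patch size; whether training patches may overlap is left to
the user). Partial windows at the right/bottom edges are dropped rather than
padded: dropped windows keep every emitted patch identically sized and
exactly traceable to slide coordinates, recorded as `{sn}_r{row}_c{col}`
with 0-based row/col origins.

Reflection padding expands e.g. a 256×256 annotation patch to the 512×512
input a model requires without altering cell morphology. The mirror excludes
the border pixel (`[1,2,3]` padded by two per side becomes
`[3,2,1,2,3,2,1]`), avoiding the 2-pixel-wide seam artifact that
border-duplicating reflection creates. Padding must be even per axis;
asymmetric padding is refused. For instance masks, every mirrored copy of a
cell receives a fresh label — one label per (reflection zone, original
label) pair — because a cell and its mirror image are distinct training
instances; letting them share a label would create a single label spanning
disconnected components.

Semantic→instance conversion labels connected foreground components 1..K in
raster order of each component's first pixel. Connectivity defaults to
8-connected (the standard for roundish nuclei blobs, where a diagonal
touch almost always means one blob) and is exposed as a flag.

Train/validation splitting is grouped by sample identifier (SN) so each
chip/section contributes proportionally: per group, a seeded shuffle
assigns round-half-up(group size × val fraction) entries to validation.
Round-half-up (rather than R's banker's rounding) keeps the count
deterministic and monotone in the fraction.

## Cell-bin expression

GEM tables (tab-delimited gene / x / y / count, with `MIDCount`-style
synonyms and `#` comment lines, optionally gzipped) are validated row-wise;
rejected rows are reported with line numbers rather than dropped silently.
Points are assigned by exact pixel lookup in the mask — coordinates are
0-based with x = column, matching the mask frame; a `one_based` flag handles
exports that count from 1, and a majority of out-of-bounds points aborts
with a coordinate-frame hint, since that symptom almost always means the
wrong convention rather than bad data.

Counts aggregate additively per (cell, gene); background points are excluded,
not redistributed. Cells with no assigned points are kept as zero rows by
default so the per-cell metadata (centroid, area) stays complete for
downstream joins. The on-disk format is an open stand-in for binary
cell-expression containers: MatrixMarket triplets plus `genes.tsv` and
`cells.tsv` sidecars — diffable, loadable by any sparse-matrix library, and
round-trip lossless.

## The synthetic generator

The generator emulates the two tissue regimes that motivate refinement, and
its defaults are the package's fixed study conditions:

* `dense_lowcontrast` — ellipses placed with a 1-pixel minimum gap and a
  foreground/background intensity gap of 3× the noise sd (cells barely
  brighter than background, as in blurred, tightly packed tissue);
* `sparse_highcontrast` — 4-pixel minimum gaps and a 10× gap.

Ellipse semi-axes are uniform on `radius_range` (default 4–8 px, nuclei-like
at ~0.5 µm/px), orientation uniform, placement by rejection sampling with a
bounded retry budget, additive Gaussian noise (default sd 8 on a 0–255
scale) clipped to range. Expression fixtures sample a fixed number of points
uniformly inside each cell, gene identities from one seeded categorical
distribution, per-point counts uniform on 1..3, plus background points at a
configurable fraction; the planted per-cell totals are returned so
conservation is checkable exactly. Each artifact is generated under its own
seed, so image, mask and points are independently reproducible.

What the fixtures do *not* emulate: staining texture inside nuclei,
overlapping/occluding cells, illumination gradients, or anisotropic point
densities. Passing tests therefore demonstrate the correctness of the
*computations* — matching, metrics, aggregation, plumbing — not segmentation
performance on real microscopy.

One consequence worth stating plainly: density is defined as N / A_total, so
two regimes compared **at matched cell count and canvas have identical
density by definition**. The regime-ordering check in the test suite
compares density with ≥ and relies on mean distance and edge contrast —
which do discriminate — for the strict orderings.

## The refinement loop

A segmenter is an adapter: `segment(image, state)` and
`finetune(entries, base_state) → state`, plus an opaque `base_state`. The
single most important contract rule is that **fine-tuning always restarts
from the original base state**, never from the previous round's state —
retraining from an already-fine-tuned model on a small, biased patch set
invites catastrophic forgetting. The test suite enforces this with a spy
adapter that records every base argument it is handed.

Each round adds one batch of annotated patches to the cumulative training
set, fine-tunes from base, evaluates on held-out pairs, and appends to a
JSON-lines log (plus CSV and a trainset snapshot) in a timestamped
`run_YYYYMMDD_HHMMSS` directory. The loop stops when mean F1 reaches the
target or after `max_rounds` — the stopping rule is this package's
operationalisation of "refine until satisfactory"; ~300 annotated cells is
a reasonable starting budget, surfaced as guidance, not enforced.

The built-in classical baseline segments by Otsu's between-class-variance
threshold, then splits touching foreground by watershed on the distance
transform, then drops components below `min_area_px` (default 15 px², about
half the area of the smallest default synthetic nucleus). It is
deterministic and, on sparse high-contrast fixtures, essentially perfect —
which is exactly what makes it a useful reference point: the loop and the
evaluation stack can be validated independently of any learned model.

## Numerical and degenerate-input choices

* All randomised operations take explicit integer seeds and restore the
  caller's RNG state.
* Masks are written as 16-bit integer TIFF (lossless up to 65 535 labels;
  more labels are refused at write time).
* Degenerate evaluation inputs (empty masks) and under-populated
  morphometric inputs return defined values or flagged `NA`s, per the
  policies above; ties in matching break by label order.
* Problem sizes in the tests and the acceptance script (64–512 px canvases,
  8–200 cells, 20–200 replicates) were chosen as the smallest sizes at which
  every property is non-trivially exercised.

## Limitations

* The perimeter estimator is exact for axis-aligned shapes and biased high
  for smooth curved boundaries; comparisons across masks are valid, absolute
  shape-complexity values are convention-dependent.
* Density and the other morphometrics are computed over the full canvas;
  images that are mostly empty glass will read as artificially sparse.
* The greedy-equals-optimal matching guarantee holds only for thresholds
  above 0.5; below that, greedy matching is a heuristic.
* Real training backends are deliberately not included; the adapter contract
  is the integration point.
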