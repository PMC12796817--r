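# segrefine

Cell segmentation refinement toolkit for spatial transcriptomics imagery.

Spatial transcriptomics platforms (e.g. Stereo-seq) pair a stained tissue
image with spot-level gene expression at sub-cellular resolution. Producing
single-cell expression profiles requires segmenting every nucleus, and
pre-trained segmentation models fail precisely where biology is most
interesting — dense, low-contrast regions such as the hippocampus. The
efficient fix is fine-tuning an existing model on a handful of annotated
patches from the failing regions. `segrefine` provides the computational
machinery around that workflow for analysts and pipeline developers:

- **patch preparation** — crop annotation patches from whole-slide images,
  reflection-pad them to a model's input size, convert binary (semantic)
  masks to per-cell instance labels, build sample-grouped train/validation
  lists;
- **instance evaluation** — one-to-one IoU matching (threshold 0.5) of
  predicted vs ground-truth cells and the five standard metrics:
  precision = TP/(TP+FP), recall = TP/(TP+FN), F1 = 2PR/(P+R),
  Jaccard = TP/(TP+FP+FN), Dice = 2TP/(2TP+FP+FN);
- **morphometrics** — six mask statistics: mean nearest-neighbour distance,
  compactness (mean distance² / mean area), density (N/A_total),
  distribution (CV of local densities 3/D<sub>i,3</sub>), shape complexity
  (mean P² / mean A), and Sobel edge contrast (μ_cell/μ_bg);
- **cell-bin expression** — map GEM expression points (gene, x, y, count)
  into a segmentation mask and aggregate per-cell counts into a sparse
  cells × genes matrix with centroid metadata, written as open
  MatrixMarket + TSV;
- **synthetic fixtures** — a deterministic generator for dense/low-contrast
  and sparse/high-contrast tissue regimes with planted ground truth;
- **the refinement loop** — a pluggable segmenter-adapter contract
  (fine-tuning always restarts from the original base weights), driven
  round by round with timestamped logs, plus a classical
  Otsu + distance-transform watershed baseline so the loop runs without any
  deep-learning backend.

## Worked example

Simulate a dense, low-contrast tissue patch, segment it with the classical
baseline, evaluate, quantify morphology, and build the single-cell
expression matrix:

```r
library(segrefine)

params <- synth_params(height = 256, width = 256, n_cells = 80,
                       regime = "dense_lowcontrast", seed = 42)
tissue <- generate_tissue(params)           # image + instance mask + truth

pred <- baseline_segment(tissue$image)
evaluate_masks(tissue$mask, pred, image_id = "dense_fixture")
#>        image_id tp fp fn precision recall        f1   jaccard      dice
#> 1 dense_fixture 80 10  0 0.8888889      1 0.9411765 0.8888889 0.9411765

morpho_report(tissue$image, tissue$mask, image_id = "dense_fixture")
#>        image_id n_cells mean_distance compactness     density distribution
#> 1 dense_fixture      80      17.78026    2.916063 0.001220703     0.191932
#>   shape_complexity edge_contrast flags
#> 1         21.00265      2.913137

expr <- generate_expression(tissue$mask, params)
ce <- cellbin(expr$points, tissue$mask)
ce
#> cell_expression: 80 cells x 20 genes, total counts 1661 (+158 background)
```

Reading the numbers: the watershed baseline recovers all 80 planted cells
(recall 1) but over-splits ten of the tightly packed ones (precision 0.89,
F1 0.94) — the characteristic failure mode that fine-tuning targets. The
morphology row says cells sit ~17.8 px apart on average at a density of
0.0012 cells per pixel (80 cells / 256²), and have edge contrast ~2.9
(boundary gradients ~3× background noise — low, as intended for this
regime). The expression matrix conserves counts exactly: 1661 in-cell plus
158 background points equals the input total.

A command-line front end over the same functions is installed at
`inst/cli/segrefine.R`:

```sh
Rscript inst/cli/segrefine.R simulate --regime dense_lowcontrast --n-cells 200 --seed 0 --out-dir fixtures/
Rscript inst/cli/segrefine.R segment --image fixtures/image.tif --out pred.tif
Rscript inst/cli/segrefine.R evaluate --gt-dir gt/ --pred-dir pred/ --iou 0.5 --out metrics.csv
Rscript inst/cli/segrefine.R cellbin --gem expr.gem --mask mask.tif --out-dir cells/
```

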