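# histofuse

Two-class classification of stained-tissue image tiles by **fusing deep
convolutional features with classical texture descriptors** — the setting
where a renal-pathology lab has a few hundred H&E tiles per class, too few to
train a deep network end to end, but enough for shallow classifiers on good
representations.

The package provides every stage as a composable, deterministic function:

1. **Stain normalization** (structure-preserving): each RGB tile is converted
   to Beer–Lambert optical densities `V = ln(I0 / I)` and factorized by
   sparse non-negative matrix factorization

   ```
   min_{W,H}  1/2 ||V − W H||_F² + λ Σ_j ||H_j,:||₁
   s.t.       W, H ≥ 0,   ||W_:,j||₂ = 1
   ```

   into a 3×r stain color basis `W` (hematoxylin-like stain first) and r×N
   density maps `H`. A source tile is re-rendered with a target's basis,
   `H_s^norm = H_s · RM(H_t)/RM(H_s)` (RM = 99th-percentile row
   pseudomaximum), `I^norm = I0 · exp(−W_t H_s^norm)`, so color styles match
   while tissue structure is untouched.
2. **Texture descriptors** from three families: HOG (oriented-gradient
   histograms with L2-Hys block normalization), GLCM properties (contrast,
   correlation, energy, homogeneity over the 15 non-empty combinations,
   averaged over 4 offsets), uniform LBP (59-bin cell histograms for 8
   neighbors at radius 1), a Gabor filter bank (mean and variance of the real
   responses per size × orientation), and Gauss-MRF neighbor-interaction
   coefficients estimated by least squares.
3. **Deep features**: an AlexNet-shaped backbone (5 conv + 3 FC layers, ReLU,
   local response normalization, overlapping max pooling) tapped at the
   4096-dimensional **fc7** layer. Weights are pluggable; seeded random
   He-initialized weights make the extractor a deterministic random
   projection, so the whole pipeline runs with no downloads.
4. **Feature selection**: dimensions of the deep block are ranked by the
   class-mean difference computed on training rows only,
   `diff_k = (1/N_pos) Σ_pos v_ik − (1/N_neg) Σ_neg v_ik`, and the top 100
   (by |diff_k|) are kept and frozen.
5. **Fusion and evaluation**: the selected deep block is concatenated with a
   texture block and classified by l2 logistic regression (C = 1), a linear
   SVM (C = 0.025), or a depth-limited random forest; accuracy, precision,
   recall and F1 are reported from the test confusion matrix
   (positive = healthy), averaged over repeated stratified 7:3 splits.

A **synthetic tissue simulator** (Beer–Lambert rendering of random nuclei
over Gauss-MRF stroma with an H&E stain basis) generates labelled fixtures,
so everything above is testable end to end without any external data.

## Worked example

```r
library(histofuse)

## separate the stains of a synthetic H&E-like tile
tile <- generateTile(tissueSimConfig(), "rc", seed = 1)
fitStainModel(rgbToOd(tile))
#> StainModel: 2 stains over 96 x 96 pixels
#>   tissue pixels: 7987 of 9216 (lambda = 0.1)
#>   W (columns = stains):
#>        [,1]   [,2]
#> [1,] 0.6500 0.0710
#> [2,] 0.7041 0.9920
#> [3,] 0.2860 0.1048
```

The first column is the recovered hematoxylin OD direction, the second the
eosin direction — matching the simulator's Ruifrok–Johnston basis to a
fraction of a degree.

```r
## the full pipeline on a small synthetic set: deep-top-100 + Gabor, SVM
res <- runPipeline(list(
  data       = list(synthetic = list(nPerClass = 20)),
  texture    = list(method = "gabor", params = list(sizes = 16)),
  classifier = "svm", nRepeats = 3, seed = 1))
res$perRepeat
#>   repeatIdx accuracy precision recall  f1
#> 1         1      100       100    100 100
#> 2         2      100       100    100 100
#> 3         3      100       100    100 100
```

Each row is one re-randomized 7:3 split; the four columns are the
percentage metrics computed from the test confusion matrix. The synthetic
classes (different nucleus density and stroma texture) are cleanly
separable at this effect size, so accuracies sit at 100%.

A command-line front end with the same stages lives at
`inst/scripts/histofuse` (subcommands `synth`, `normalize`, `extract`,
`deepfeat`, `fuse`, `train-eval`, `run`).

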