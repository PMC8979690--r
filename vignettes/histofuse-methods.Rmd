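---
title: "Methods: deep–texture fusion for stained-tissue tile classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep–texture fusion for stained-tissue tile classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

histofuse implements a small-data histopathology classification strategy:
instead of training a deep network end to end on a few hundred tiles, it
combines a fixed convolutional feature extractor with classical texture
descriptors and hands the fused representation to shallow classifiers. This
vignette records the models, the parameter choices and the numerical
decisions behind each stage, and what the synthetic test bed does and does
not establish.

## Stain model and color normalization

H&E-stained tissue transmits light according to Beer–Lambert: if `I0` is the
incident intensity, the transmitted RGB intensity of a pixel with stain
concentrations `h` is `I = I0 exp(−W h)`, where the columns of the 3×r
matrix `W` are the optical-density colors of the stains. Working in OD space
(`V = ln(I0/I)`) makes stain mixing linear, so stain separation becomes a
non-negative factorization `V ≈ W H` with an L1 penalty on the density rows
and unit-norm columns of `W`:

* `i0 = 255` (8-bit convention); intensities are clipped to `[1, i0]` before
  the logarithm so OD is finite.
* Background exclusion: pixels whose maximum channel OD is below **0.15**
  (near-white glass) are excluded from fitting and passed through
  normalization unchanged. Configurable.
* Stain count `r = 2` (hematoxylin + eosin) by default; the solver accepts
  any `r ≥ 1` for exotic protocols.
* Sparsity weight `λ = 0.1` by default, in OD·pixel units.

**Solver.** The penalized problem is solved by block coordinate descent
(HALS): each density row has the closed-form minimizer
`H_j = max(W_jᵀR_j − λ, 0)` and each basis column the closed-form minimizer
`W_j = (R_j H_jᵀ)⁺ / ||(R_j H_jᵀ)⁺||`, i.e. projection onto the non-negative
unit sphere. Every substep is an exact block minimization, so the objective
is non-increasing at every iteration and the unit-norm constraint holds
throughout — both are machine-checked in the test suite. For `r = 2` the
basis is initialized geometrically at the robust extreme angles (1st/99th
percentile) of the OD cloud in its top-2 singular plane; other `r` start
from a seeded random draw.

**Debiasing polish.** L1 shrinkage biases both the concentrations and,
through the coupled updates, the fitted basis. The returned model is
therefore the *unpenalized* local refinement of the sparse solution: after
the penalized stage converges, the same block updates are run with `λ = 0`
from the sparse iterate (the lasso-then-least-squares idiom). The sparse
stage fixes the identification — which basin the estimate lives in — and the
polish removes the shrinkage so that self-normalization reproduces a tile to
within ±2 intensity levels, which the test suite asserts. The recorded
objective trace covers the penalized stage.

Normalization scales each source density row by the ratio of target to
source **robust pseudomaxima** — the 99th percentile of the row, computed
with linear interpolation between order statistics (R's type-7 quantile;
fixed so results are reproducible). A zero source pseudomax would divide by
zero; that stain's scale factor falls back to 1 with a warning.

## Texture descriptors

All descriptors operate on the ITU-R BT.601 luma of the tile (fixed
convention) and are pure functions: identical input and configuration give
bit-identical output.

**HOG.** Square-root gamma compression; central-difference gradients;
unsigned orientations on [0°, 180°) in 9 bins with linear interpolation
between neighboring bin centers; cells of 6 px, blocks of 4×4 cells sliding
by one cell, L2-Hys normalization (clip at 0.2, renormalize; all-zero blocks
stay zero rather than dividing by zero). The descriptor length follows
`(nCells − block + 1)² · block² · 9`, verified across the conventional
{6, 8} × {2..5} cell/block grid.

**GLCM.** Ordered pair counts at distance `d = 1` for angles
{0°, 45°, 90°, 135°}, quantized to 8 levels over [0, 255] by default.
Counting is non-symmetric (ordered pairs); reversing the offset transposes
the matrix, which the tests exploit. Properties use level indices 0..N−1:
contrast `ΣP(i,j)(i−j)²`, energy `ΣP²`, homogeneity `ΣP/(1+(i−j)²)`, and
*standard* Haralick correlation `Σ(i−μᵢ)(j−μⱼ)P/(σᵢσⱼ)` — the moment-based
form that keeps correlation in [−1, 1], with the marginal means and SDs
taken from the normalized matrix. A single-level (zero-variance) matrix has
no defined correlation; it is reported as 1 with a degeneracy flag. The 15
property combinations are emitted in the fixed order contrast, correlation,
energy, homogeneity, averaged over the four angles.

**Uniform LBP.** 8 neighbors at radius 1 use the classic 3×3 window, bits
read left-to-right, top-to-bottom with the first-read bit most significant;
other (P, R) sample a circle with bilinear interpolation. A neighbor
at least as bright as the center codes 1, so adding a constant to the image
changes nothing. Uniform patterns (≤ 2 circular transitions) get their own
bins ordered by decimal code, all non-uniform codes share one bin —
`P(P−1)+3 = 59` bins for P = 8. Cell histograms (16-px cells by default) are
L1-normalized; unnormalized histograms conserve the coded-pixel count, a
tested invariant.

**Gabor bank.** Kernels
`exp(−(x′² + γ²y′²)/(2σ²))·cos(2πx′/λ)` on a size×size grid; defaults
λ = size/4, σ = 0.56·λ, γ = 0.5, orientations {0°, 45°, 90°, 135°}, sizes
4:4:32. Convolution is FFT-based with reflected boundaries; features are the
mean and variance of each real response. A matched sinusoidal grating excites
a filter strictly more than the orthogonal one (tested).

**Gauss-MRF coefficients.** The centered luma is modelled as a conditional
autoregression: the conditional mean of a pixel given the rest of the image
is `Σ_r β_r (x_{s+o_r} + x_{s−o_r})` over symmetric offset pairs (default:
horizontal and vertical nearest neighbors). The field's texture is
summarized by the least-squares estimates of `β` plus the residual variance.
The normal equations are solved by cyclic coordinate descent run for
`nIterations` sweeps (default 20; the conventional tuning grid is 20:10:50),
which is deterministic and makes the iteration count an explicit, sweepable
parameter. For a Gaussian field the conditional expectation is linear in the
neighbor sums, so the least-squares projection is consistent; the tests
verify recovery of β = (0.24, 0.24) to ±0.05 on a 256×256 simulated field
and near-zero estimates on white noise. Constant images short-circuit to
zero coefficients with a warning. Which functionals of an MRF to use as
features is a genuine design choice; interaction coefficients plus noise
variance is the interpretation implemented here.

## Deep feature extractor

The backbone is the classical 8-layer AlexNet shape: conv 96@11×11/4,
256@5×5, 384@3×3, 384@3×3, 256@3×3 with ReLU everywhere, local response
normalization after the first two convolutions (k = 2, α = 1e-4, β = 0.75,
n = 5 — the classical constants), 3×3/2 overlapping max pooling, then
fc6 (9216→4096), fc7 (4096→4096), fc8. Features are the post-ReLU **fc7**
activations, 4096 per image regardless of content.

Weights are a plug-in. By default they are a seeded He-normal
initialization (`sd = sqrt(2/fan_in)`), which keeps activation magnitudes of
order one through the stack and makes the extractor a reproducible random
projection — random convolutional features are a legitimate, if weaker,
representation, and they keep the test suite free of any download. Trained
weights can be supplied as an RDS file; a mismatch against the architecture
is reported naming the first offending layer.

Preprocessing resizes the shorter side to 224, center-crops, and
standardizes channels with the ImageNet constants (configurable).

The optional finetuning hook trains the fully-connected stack by full-batch
gradient descent on softmax cross-entropy with early stopping on validation
accuracy (`patience` epochs without improvement). The convolutional layers
stay frozen: with tens to hundreds of tiles, fitting 3.7M convolutional
parameters is not meaningful, and freezing makes the hook cheap and
deterministic. Which layers to adapt is an open choice; this is the one
implemented and documented. Epoch budget and patience are explicit
parameters rather than constants because no single pair of values suits the
range of dataset sizes the package targets.

## Selection, fusion, evaluation

The deep block is pruned by the **class-mean difference**: for each
dimension, the difference between the positive-class and negative-class
training means. Ranking uses |diff| by default — a dimension strongly
favoring either class is informative, and a signed ranking would silently
discard negative-class markers; `signed = TRUE` restores the literal signed
ordering. Ties break toward the lower dimension index, making the
permutation unique. The ranking object stores the training-row ids and is
applied frozen to validation rows, so selection can never be re-fit on
pooled data through the public interface. `k = 100` of 4096 by default.

Fusion is horizontal concatenation, deep block first, with per-column
provenance labels. No rescaling is applied by default; an optional z-scoring
flag standardizes columns with means and SDs fitted on a stated set of
training rows only.

Classifiers follow the conventional small-data settings: l2 logistic
regression with C = 1.0 (ridge logistic via glmnet, `lambda = 1/(nC)`, no
internal standardization), a linear SVM with C = 0.025 (e1071, no scaling),
and a random forest of 100 trees with at most 8 leaves per tree — the
depth-3 regime that keeps individual trees weak. Metrics are computed from
the test confusion matrix under the convention **positive = healthy
tissue**. Two modes are provided: `"standard"` (precision = tp/(tp+fp),
recall = tp/(tp+fn)) and `"as_printed"` (precision = tp/(tp+fn),
recall = tn/(tn+fp)), the latter reproducing a nonstandard but published
variant — precision over false negatives, recall as specificity — for
comparability; both agree whenever fn = fp, and F1 is always the harmonic
mean of the mode's own precision and recall. Zero denominators yield 0 with
a flag instead of NaN.

"Repeated evaluation" draws a fresh stratified 7:3 split *and* a fresh
classifier seed per repeat (10 by default); whether historical experiments
re-drew their splits is usually unstated, and re-drawing is the
statistically safer reading because it averages over split noise.

## The synthetic test bed

`tissueSimConfig()` renders tiles through the same Beer–Lambert model the
normalization assumes: a hematoxylin density map of soft random nuclei over
an eosin stroma field, mixed by the unit-normalized Ruifrok–Johnston H&E OD
basis and exponentiated. Class signal is deliberately carried on two
channels: nucleus count per tile (healthy 25 vs tumor-like 55 — chromatin
density is the classic nuclear marker) and the stroma's Gauss-MRF
coefficients (healthy isotropic (0.22, 0.22) vs anisotropic (0.05, 0.38) —
directional fibrosis-like texture), with density-space noise SD 0.02. Tiles
are 96×96: large enough for stable texture statistics and stain geometry,
small enough that the full pipeline, including the convolutional forward
pass, runs in minutes. Augmentation applies the lossless group
{rot90, rot180, rot270, hflip}; the variant set is explicit per call because
real augmentation ledgers often differ per class, and the splitter keeps all
variants of a source tile on one side of the split (group-aware, on by
default) since augmented copies leak label information across splits
otherwise.

What the simulator does **not** emulate: optical blur and chromatic
aberration, stain co-localization beyond the linear two-stain model,
nucleus morphology (ellipticity, clustering, chromatin texture), scanner
noise statistics, and the sheer heterogeneity of real tissue. Passing tests
therefore establish that the pipeline's machinery is correct and that its
stages compose — recovery of known generative parameters, conservation
laws, frozen-selection discipline, directional superiority of fusion on
this task — not that any particular accuracy transfers to clinical images.
At the default effect sizes the synthetic task is cleanly separable, so
accuracies saturate near 100% and the fusion comparison typically shows
ties at the top rather than gaps.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation (type 7), everywhere.
* OD clipping at intensity 1 avoids log(0); reconstruction clips to [0, i0].
* Stain ordering: the column with the larger blue-channel OD weight
  (hematoxylin binds nuclei and absorbs red/green, leaving blue large) is
  first, so bases are comparable across tiles.
* All-zero HOG blocks, constant-image LBP/GLCM/MRF inputs, empty
  backgrounds, single-class label vectors and zero metric denominators all
  have explicit, tested behaviors (zeros, warnings, or errors naming the
  offending input).
* Every stage seed derives from one master seed through a fixed counter
  scheme (`(seed·7919 + counter·104729) mod (2³¹−1)`), so stages are
  independently reproducible and a pipeline rerun is bit-identical.
* Normalization precedes augmentation in the pipeline; per-pixel color
  mapping commutes with the geometric group, and normalizing originals is
  r-fold cheaper.

## Problem sizes used by the checks

The test suite and the acceptance script size their simulations to
commodity hardware as a deliberate design choice: texture oracles run on
images up to 8×8 (exhaustive pair enumeration) and 3×3–4×4 probability
matrices (double loops); MRF recovery uses one 256×256 field; the fusion
comparison uses 100 tiles per class at 96×96 with five re-splits, the same
conditions the directional claim is stated for. Larger tiles and deeper
sweeps only change runtimes, not the code paths exercised.

## Known limitations

* The default deep features are random projections; with pre-trained
  weights the same interface yields stronger features, but no weights ship
  with the package.
* The HALS stain solver is exact per block but, like all NMF, only locally
  optimal; the geometric initialization makes the two-stain case reliable,
  `r > 2` inherits the usual sensitivity to initialization.
* GLCM distances beyond `d = 1` are a config knob, not a tuned path;
  rotation-invariant LBP variants and multiscale HOG are out of scope.
* The random-forest stage caps leaves (8) rather than literal depth, and
  splits by the Gini criterion — the impurity choice available in the
  underlying implementation; at depth 3 the two criteria rarely disagree.
* Whole-slide images are out of scope; the unit of analysis is the tile.
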