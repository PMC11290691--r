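---
title: "Screening cytopathology tiles with cytoscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cytopathology tiles with cytoscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cytoscreen` implements a two-stage screening pipeline for cytopathology
image tiles: a nested dense-skip U-Net segments cell clumps out of noisy
backgrounds, and a label-supervised contrastive classifier calls each
extracted clump benign or malignant. This vignette explains the models,
the parameters that matter, the synthetic data the package tests itself
on, and the design decisions taken where the design was genuinely open.

## The screening problem

On a cytology slide, the diagnostic unit is the *cell clump*: a connected
cluster of epithelial cells. The background between clumps carries single
cells, leukocytes and debris that must not reach the classifier. Slides
arrive in two common staining protocols — hematoxylin/eosin (pink/purple)
and Papanicolaou (blue/green) — and a useful screening model has to be
robust to that palette shift. The clinically costly error is the false
negative: a malignant clump called benign.

The pipeline mirrors how a cytopathologist works: find the clumps, then
judge each one. Whole-slide scans are cropped into fixed-size tiles;
tiles whose pooled RGB mean lies in $[50, 230]$ and whose pooled standard
deviation exceeds 20 are retained (empty glass has low spread, saturated
regions an extreme mean). Kept tiles are segmented, the mask is cleaned
morphologically, each 8-connected component becomes a region of interest
(ROI) zero-padded onto a fixed square canvas, and each ROI is classified.

## Stage one: nested dense-skip segmentation

The segmenter is a U-Net variant organized as a triangular grid of nodes
$X^{i,j}$, where row $i$ halves the spatial resolution and column $j$
counts refinement steps. The encoder spine is the usual chain
$x^{i,0} = H(D(x^{i-1,0}))$; every other node consumes *all* same-row
predecessors plus one upsampled map from the row below:

$$x^{i,j} = H\big(\big[x^{i,0},\dots,x^{i,j-1}, U(x^{i+1,j-1})\big]\big),$$

with $H$ a small convolution block, $D$ 2×2 max pooling, $U$ nearest
×2 upsampling and $[\cdot]$ channel concatenation. A grid of depth $d$
has $(d+1)(d+2)/2$ nodes; row 0 stays at full resolution, which is where
supervision attaches.

**Channel attention.** At the bottleneck $x^{d,0}$ the feature map is
flattened to $K$ channel vectors and reweighted by pairwise affinities:
row $b$ of the affinity matrix is the softmax over $a$ of $x_a \cdot
x_b$, and the output is the residual mix $E_b = \beta \sum_a M_{ba} x_a +
x_b$ with a learned scalar $\beta$ initialized at 0 — an untrained module
is exactly the identity, so attention is phased in only as far as it
helps. A degenerate variant that normalizes by the self-similarity
$x_b\cdot x_b$ (making the softmax constant along its row) is retained
behind `ca$literal_eq2` for inspection only; it is not a trainable form,
and the package refuses to run forward passes with it.

**Multi-level semantic supervision.** Each full-resolution node
$x^{0,j}$, $j = 1..d$, gets a 1×1 convolution head producing class
logits. The side loss is the weighted sum of per-level hybrid losses with
weights $\alpha$ ordered from the earliest column to the final one; the
default takes the last $d$ values of $(0.1, 0.3, 0.6, 0.9)$, so the
final, most refined prediction carries the largest weight. Supervising a
side output requires a loss, not a raw output, which is how the package
interprets deep supervision throughout; a global-average-pooling scalar
side path is not reconcilable with dense per-pixel supervision and is
deliberately not implemented.

**Hybrid loss.** Per pixel and class the loss combines cross-entropy with
a Dice-style overlap reward:

$$L_{T,P} = -\frac{1}{N}\sum_{c=1}^{C}\sum_{n=1}^{N}\Big(t_{n,c}\log
p_{n,c} + \frac{2\,t_{n,c}\,p_{n,c}}{t_{n,c}^2 + p_{n,c}^2 +
\varepsilon}\Big),$$

where $N$ is the pixel count of the batch. The overlap term rewards
confident foreground hits, counteracting the class imbalance of sparse
clumps on large backgrounds; at a perfect prediction each true pixel
contributes exactly $-1$, so the loss is negative by construction.
$\varepsilon = 10^{-7}$ defines the $0/0$ case at $t = p = 0$ as 0, and
probabilities are clamped to $(\varepsilon, 1-\varepsilon)$ inside the
logarithm. The total loss is $L = L_{T,P}(\text{final}) + L_{side}$. A
config flag `loss$literal_eq6` instead multiplies this sum by the depth
$d$ — a printed d-fold summation whose terms do not depend on the
summation index; it rescales the objective without changing its
minimizers, and the default keeps the unscaled form.

**Training.** Adam with learning rate $5\times10^{-3}$ and batch size 32
(the defaults), with on-the-fly flip/rotation/grayscale augmentation.
Training is fully reproducible from the config seed. The backbone is a
compact convolution-block encoder whose depth, widths and
convolutions-per-block are configuration; a deeper residual backbone is a
choice the same grid code admits, not a requirement of the architecture.
At desk scale one convolution per block (`block_convs = 1`) trains
markedly faster and escapes the all-background plateau earlier, which is
why the package's own experiments use it.

## Stage two: label-contrastive ROI classification

Each ROI canvas is encoded by a small convolutional network ending in
global average pooling, from which two heads branch: a softmax classifier
and a projection to a $D$-dimensional embedding, L2-normalized. A
*momentum encoder* — a structural copy whose parameters follow
$\theta_k \leftarrow m\,\theta_k + (1-m)\,\theta_q$ with $m = 0.9$ and
receives no gradients — encodes the same images into *keys*, which are
pushed with their labels into a fixed-capacity FIFO *memory bank*
(default 4096).

For a query embedding $q$ with label $y$ against bank keys
$(k_i, y_i)$:

$$L_{con} = -\log\frac{\sum_{i: y_i = y} \exp(q\cdot k_i/\tau)}
{\sum_i \exp(q\cdot k_i/\tau)}, \qquad \tau = 0.07.$$

The loss is zero exactly when every key shares the query's label and
equals $-\log(n_{pos}/n)$ whenever all similarities coincide. Positives
come from *labels*, not augmented views: two clumps of the same class are
pulled together in embedding space even when their palettes differ,
which is the mechanism that buys staining robustness. Cosine similarity
(dot product of unit vectors) is the similarity function — the natural
choice for the memory-bank lineage this design follows. The classifier
loss is standard cross-entropy over the query head (an indicator that
selects the *true* class; an indicator of *correct classification* would
silence the loss exactly on the samples that need gradient), and the
total objective is $L_{cla} + \beta L_{con}$ with $\beta = 0.5$.

Practical details: the contrastive term stays disabled until the bank
holds at least one key of every class (warm-up); a query whose label has
no positive key signals a typed skip-sample condition rather than
returning infinity; keys are renormalized with a warning if they arrive
off the unit sphere; prediction ties break toward `"malignant"` because
screening favors sensitivity.

## The synthetic tile generator

Real cytology collections are rarely shareable, so the package carries a
seeded generator that emulates the features the pipeline must handle:

- 0–10 *cell clumps* per tile: radially perturbed ellipses with
  multiplicative value-noise texture standing in for chromatin.
- Class-dependent boundaries: benign clumps perturb the radius by a
  low-order Fourier series with total amplitude 4% of the radius;
  malignant clumps use 30% plus 1–3 narrow Gaussian protrusions. The
  benign/malignant distinction is thus an explicitly *geometric* property
  (neat versus irregular edges), measurable as perimeter²/area.
- Background speckles (discs ≤ 6 px across) that appear in the image but
  never in the mask — the "noise" the segmenter must reject.
- Two palettes over identical geometry: H&E-like pink/purple and
  Papanicolaou-like blue/green, both strictly monotone in luminance, so
  the ground truth is stain-invariant by construction.
- A default malignant fraction of 0.6, mirroring the roughly 60/40
  positive/negative balance typical of screening collections.

The same spec and seed produce byte-identical tiles; all randomness is
scoped with `withr::with_seed`, leaving the caller's RNG untouched.
Clumps are placed by rejection sampling with a minimum 4 px separation
(so the component count always matches the clump list); on crowded tiles
the drawn radius shrinks geometrically until placement succeeds rather
than failing the count contract.

What the generator does *not* emulate: nucleus-level structure, stain
bleed, overlapping clumps, focus artifacts, or scanner noise. Passing the
package's tests therefore demonstrates that the machinery — losses,
gradients, bank dynamics, pipeline plumbing — recovers a known signal at
desk scale, not that the models reach clinical performance on real
slides.

## Numerical and design choices

- **Background filter**: mean bounds inclusive, standard deviation
  strictly greater than the threshold ("above"); statistics pooled over
  all pixels and channels. A per-channel variant was considered and
  rejected to keep the rule a single scalar pair.
- **Tiling**: non-overlapping by default; edge remainders are dropped
  rather than padded so synthetic borders never contaminate the filter
  statistics.
- **Connectivity**: 8-connected components, so clumps touching
  diagonally count as one lesion. Components below `min_area` (default
  64 px at synthetic scale) are discarded.
- **ROI canvas**: masked crop (background zeroed) centered on the zero
  canvas; oversized clumps are downscaled preserving aspect ratio, never
  cropped, preserving morphology over scale.
- **Empty-vs-empty Dice** is defined as 1: an all-background tile
  predicted as all background is a perfect prediction.
- **Undefined metrics** (zero denominators) are reported as `NA`, never
  silently 0, so cross-validation means stay unbiased.
- **ROC**: threshold sweep over unique scores with ties grouped,
  trapezoidal AUC; verified against an established implementation and a
  rank-statistic identity in the test suite.
- **Cross-validation folds** are grouped at the source-image level so
  ROIs from one tile never straddle a train/test boundary.
- **Segmentation of non-divisible shapes** reflect-pads to the next
  multiple of $2^d$ and crops back, a contract rather than an error.

## Problem sizes used by the package's own experiments

The bundled experiments are sized for a single CPU: segmentation
recovery trains a depth-2 grid (widths 8/16/32, one convolution per
block) on 200 generated 128×128 tiles in mixed palettes, monitoring Dice
on a held-out fifth; classification recovery trains the compact encoder
(input 64, widths 8/16/32, embedding 64) on a few hundred generated ROIs
with both palettes mixed. The contrastive ablation compares β = 0.5
against β = 0 pairwise over five seeds with identical budgets on the
*cross-stain* split — training on H&E-rendered ROIs and testing on
Papanicolaou-rendered ones — because style robustness is precisely the
property the label-contrastive term targets. (At very short budgets the
plain cross-entropy arm can converge faster on an in-distribution split;
the contrastive term's benefit shows in generalization, not raw fitting
speed, which is why the ablation is scored on the cross-stain split at a
budget where both arms have converged.) The comparison is on median
held-out accuracy.

## Known limitations

- The networks run on the package's own CPU convolution engine; it is
  exact (gradients verified against finite differences) but not fast
  enough for clinical-scale training, which is out of scope here.
- The one-versus-two-stage and ablation comparisons are directional
  checks on synthetic data, not effect-size estimates.
- The generator's irregularity parameters operationalize qualitative
  morphology criteria ("neat" versus "irregular" edges); they are a
  modeling choice, not measurements.
- Watershed separation of touching clumps and nucleus-level analysis are
  out of scope.
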