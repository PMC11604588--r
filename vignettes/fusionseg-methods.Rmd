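---
title: "Dual-decoder fusion segmentation: model, metrics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-decoder fusion segmentation: model, metrics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionseg)
```

## The problem and the model

Glioblastoma MRI studies annotate three tumor subregions — necrotic core
(NC), peritumoral edema (ED) and enhancing tumor (ET) — on co-registered
FLAIR, T1, contrast-enhanced T1 (ceT1) and T2 volumes. `fusionseg`
implements FusionNet, a 3D semantic-segmentation network that combines the
two classical decoder designs:

* a **shared encoder** of 13 convolutional layers arranged in five blocks of
  (2, 2, 3, 3, 3) convolutions — the VGG16 convolutional layout — each block
  ending in a 2× max-pooling that records its argmax indices;
* a **skip-connection decoder** (U-Net style): trilinear 2× upsampling,
  concatenation with the matching encoder feature map, convolution;
* a **pooling-index decoder** (SegNet style): max-unpooling with the
  recorded indices (zeros elsewhere), convolution, no skip concatenation;
* a **fusion head** joining the two decoders' full-resolution feature maps
  by elementwise addition (mode A), elementwise multiplication (M) or
  channel concatenation (C), followed by one shared 1×1×1 convolution and a
  per-voxel softmax over the class channels.

Because both decoders read one and the same encoder pass, the bottleneck
features they consume are bitwise identical; the fusion mode is the only
difference between the three model variants.

Training minimizes unweighted voxelwise cross-entropy,
$L = -\tfrac{1}{HWD}\sum_{h,w,d}\sum_c y_{hwdc}\log\hat y_{hwdc}$,
with plain stochastic gradient descent and an exponentially decaying
learning rate $\eta_e = \eta_0\,\gamma^e$ (defaults $\eta_0 = 0.01$,
$\gamma = 0.8$ per epoch, 20 epochs, batch size 5). Class imbalance is
addressed only through the data, not through loss weights.

The entire network — 3D convolution, batch normalization, ReLU, pooling
with indices, unpooling, trilinear upsampling, softmax cross-entropy and
its analytic backpropagation — is implemented in this package with C++
compute kernels, and the gradients are verified against central finite
differences in the test suite.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `base_width` | 8 | channels of encoder block 1; later blocks double (8, 16, 32, 64, 128), optionally capped by `max_width` |
| `num_blocks` | 5 | encoder depth; each block halves the edge, so `input_edge` must be divisible by `2^num_blocks` |
| `input_edge` | 256 | cubic input edge in voxels; 32 or 64 for CPU-scale work |
| `fusion_mode` | A | A = add, M = multiply, C = concatenate the decoder outputs |
| `lr0`, `decay` | 0.01, 0.8 | SGD step size and its per-epoch exponential decay |
| `epochs`, `batch_size` | 20, 5 | optimization budget |

Only the first block's width is fixed by the architecture description; the
doubling progression is this package's choice, proportional to VGG16, and
`max_width` exists because at full scale memory, not accuracy, constrains
the widths.

Convolutions are 3×3×3, stride 1, zero padding 1, each followed by batch
normalization (the SegNet convention) and ReLU. The skip decoder upsamples
with trilinear interpolation followed by convolution rather than transposed
convolution, avoiding checkerboard artifacts. The classifier sits after
fusion (fused-then-classified), reading the joint output layer as one
shared head. Weights use He initialization, the standard scheme for ReLU
networks; the seed is recorded with every checkpoint.

## Data handling

Native volumes (e.g. 240×240×155) are zero-padded to the smallest
power-of-two cube, 256³, with the content centered and the extra voxel of
an odd margin on the high side: margins (8, 8), (8, 8), (50, 51). Padding
records its margins and is exactly reversible.

Augmentation applies horizontal flip, vertical flip and 90/180/270-degree
rotations. "Horizontal/vertical" are interpreted in the axial plane of the
canonically oriented volume; the slice axis is never flipped, because
left–right and anterior–posterior reflections are anatomically plausible
while head–foot reflection is not. Every transform is a pure index
permutation applied identically to all modality channels and the label map
— labels are never interpolated — so per-class voxel counts are invariant.
A 500-subject training set expands to exactly 3,000 samples (originals plus
five transforms each). Augmentation happens strictly after the
train/validation/test split, so no transformed copy of a validation or
test subject can leak into training. It is materialized eagerly; at desk
scale the memory cost is trivial and eager expansion keeps epochs
deterministic.

BraTS-style label files encode classes as {0, 1, 2, 4}; loaders remap 4 → 3
to contiguous classes and invert the mapping on save.

## Evaluation metrics

Per subregion class and subject, from the voxel confusion counts (TP, FP,
TN, FN):

* recall TP/(TP+FN), precision TP/(TP+FP), Dice 2TP/(2TP+FP+FN) — the
  harmonic mean of precision and recall;
* LFPR, the lesion false positive rate FP/(FP+TN). Raw values are reported;
  they are naturally small because background dominates the volume, and no
  rescaling is applied (any normalization for display is a presentation
  choice, not part of the metric);
* AVD, the average relative volume difference |V_pred − V_true| / V_true,
  computed per subject per class (one volume pair per subject, matching
  per-class reporting), with zero-truth-volume subjects excluded and
  counted;
* ASSD, the average symmetric surface distance: surfaces are the mask
  voxels with at least one of six face-neighbors outside the mask (the
  volume border counts as outside), taken at voxel centers in physical
  units; distances are Euclidean nearest-neighbor, averaged in both
  directions and halved. The implementation uses a uniform-grid spatial
  index with shell-expansion search; tests compare it against an all-pairs
  brute force.

Undefined values propagate as NaN and are excluded from cohort means with
their exclusion count reported, never silently averaged: recall and Dice
are undefined when the truth class is absent, LFPR when there are no
negatives, and ASSD when either surface is empty (the convention for a
method that predicts no lesion). An empty prediction against a non-empty
truth scores 0 on recall, precision and Dice. Precision of an empty
prediction is defined as 0 rather than NaN so that a never-predicting
method scores 0, matching how absent predictions appear in published
result tables. Cohort aggregation reports mean ± SD with the population
(divide-by-n) standard deviation.

## The phantom generator

Phantoms stand in for patient data so the full pipeline runs with no
external downloads. Each phantom is three nested ellipsoids — NC inside ET
inside ED — around a jittered center, with one set of random axis ratios in
[0.7, 1.3] shared by the shells (guaranteeing nesting; anisotropy makes
flips and rotations produce genuinely distinct samples). Default radii
(20, 13, 7) voxels on a 64-voxel grid put the tumor at roughly a fifth of
the volume, a realistic whole-tumor fraction for a conspicuous
glioblastoma at this resolution; desk-scale tests use a 32-voxel grid with
radii (10, 6.5, 3.5). Each modality channel is a per-region intensity
lookup, Gaussian-blurred (SD 0.8 voxels, emulating partial-volume softening
of boundaries) plus Gaussian noise (SD 0.05 on the 0–1 intensity scale).

The default intensity table encodes the qualitative contrast of the four
sequences: FLAIR and T2 brightest in edema, ceT1 brightest in the enhancing
rim with a dark necrotic core, T1 low-contrast across tumor regions. The
generator is seed-deterministic (R's default Mersenne–Twister), and cohort
generation derives per-subject seeds from one master seed.

What the phantoms do **not** emulate: scanner physics, bias fields,
multifocal or infiltrative growth, annotation ambiguity, skull or
anatomical background. Passing tests on phantoms therefore demonstrate
that the architecture, loss, optimization and metrics are implemented
correctly and that the network can learn multimodal contrast structure —
not that it reaches any particular accuracy on patient data.

## Numerical choices and degenerate inputs

* Predicted probabilities are clamped at 1e-12 before the log, so a
  degenerate zero probability yields a large finite loss.
* Softmax subtracts the per-voxel maximum before exponentiation.
* Argmax labeling breaks ties toward the lowest class index,
  deterministically.
* Batch-norm statistics are per channel over the whole batch volume, eps
  1e-5, running-moment momentum 0.1; inference uses running moments.
* Max-unpooling validates every index against its own 2×2×2 window and
  rejects corrupted states.
* The trilinear upsampler uses the align-corners-false convention (edge
  samples clamp), and its adjoint is used in backpropagation.

## Problem sizes used in the checks

The test suite and the acceptance script exercise the published
arithmetic — 500 → 3,000 augmentation, 240×240×155 → 256³ padding, the
611 = 500/31/80 split — at full size, and run training at desk scale: a
32-voxel edge, base width 4, three blocks, two modalities (FLAIR + ceT1).
Under those conditions a single phantom is overfit to whole-tumor Dice
above 0.9 within 200 SGD steps, and a 20-phantom cohort (14 train
subjects, sixfold-augmented to 84 samples; 3 validation; 3 test) trains
for 5 epochs in a few minutes on one CPU with strictly decreasing loss.
These sizes were chosen so a complete run stays interactive on a laptop;
the constant learning rate 0.1 used for the overfit check (decay 1) is the
standard choice for demonstrating trainability, where decay would only
slow memorization. At 5 cohort epochs the network reliably learns the
whole-tumor extent and the edema shell, while the small NC/ET cores
require a longer budget — the reported per-subregion Dice values at desk
scale reflect the training budget, not a ceiling of the architecture.

## Known limitations

* Full-scale (256³, five blocks, 3,000 samples, 20 epochs) training is far
  outside CPU reach; the package reproduces the method, its arithmetic and
  its evaluation conventions, not the published cohort metrics, which
  require the original patient data and GPU-scale training.
* Single-threaded compute kernels; no GPU or SIMD-explicit path.
* The modality-sweep harness trains one model per subset sequentially; at
  desk scale this is minutes, at full scale it would be days.
* No 2D variant and no additional loss terms (Dice or composite losses)
  are provided; the training objective is cross-entropy only.
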