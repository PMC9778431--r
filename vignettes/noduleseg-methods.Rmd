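---
title: "Methods: complementary feature decoding for lung nodule segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complementary feature decoding for lung nodule segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleseg)
```

## The problem

Pulmonary nodules on CT vary enormously in size, shape and intensity, and the
hardest cases -- ground-glass opacities, wall-attached (juxta-pleural) and
vessel-attached (juxta-vascular) nodules -- share their intensity with the
surrounding tissue. `noduleseg` implements a segmentation network organised
the way a radiologist works: first locate the nodule, then delineate its
coarse area, then refine the boundary, and let the three kinds of information
complement each other.

## Model

**Backbone.** A five-level, Res2Net50-style feature extractor. The usual 7x7
stem convolution is replaced by three consecutive 3x3 conv+ReLU layers (first
stride 2), and there is no pooling tail or classification head. Taps f1..f5
sit at strides (2, 4, 8, 16, 32); f1/f2 are the low-level, edge-rich
features, f3/f4/f5 the high-level semantic ones. Stride-1 bottlenecks use the
hierarchical 4-way split of 3x3 convolutions; the first (stride-2) block of
each stage is a plain bottleneck with a strided 3x3 and a strided 1x1
shortcut. A width multiplier and per-stage block counts let tests run a
desk-scale network with the same topology.

**MF block (multi-receptive-field refinement).** Each high-level feature
passes through four cascade branches b0..b3: a 1x1 channel reduction to 32,
then for branch m >= 1 a factorized 1x(2m+1) and (2m+1)x1 pair followed by a
3x3 convolution with dilation rate 2m+1. Composing kernel extents along a
stride-1 chain (the field grows by (k-1)d per layer) gives effective
receptive fields of 1, 9, 15 and 21 pixels for the four branches --
`branch_receptive_field()` computes exactly this composition. The branch
outputs are concatenated (128 channels), reduced to 32 by a 3x3 convolution,
and a 1x1-projected shortcut is added elementwise.

**MD block (cross-scale decoding).** The refined features f3', f4', f5' are
aggregated progressively: the deepest passes through unchanged (f5'' = f5'),
and each shallower level is multiplied elementwise by 3x3-convolved (with
batch normalization), bilinearly upsampled copies of every deeper level:

f4'' = f4' * Conv(Up(f5')),  f3'' = f3' * Conv(Up(f4')) * Conv(Up(f5')).

The three maps are aligned at f3 resolution, concatenated, and a head of two
3x3 convolutions plus a 1x1 convolution produces the coarse nodule logit map
fg. No activation follows the BN in the gating convolutions, so the
multiplicative weighting stays signed.

**LE block (edge decoding).** The low-level features are fused as
fE = f2 + f1 * f2 after projecting both to 32 channels; the sum keeps
complementary features, the product amplifies edges both levels agree on. fE
lives at f2's resolution (stride 4): f1 is pooled down rather than f2
upsampled, which keeps the high-resolution edge path cheap.

**Complementary module.** Location fusion gates f4' with a sigmoid of the
convolved, upsampled f5' and adds the result pointwise to fE, giving the
final edge guidance fE^. Edge fusion adds the convolved, upsampled coarse
map to fE^ in logit space, projects to one channel, upsamples bilinearly to
the input resolution and applies a sigmoid, yielding the segmentation
probability map Ps. A 1x1 sigmoid head on fE^ provides the edge probability
map used for supervision; the addition in edge fusion happens pre-sigmoid
(logit-space), which keeps the fusion linear where the supervision acts.

## Loss

Every pixel receives a weight W = alpha + beta |Gs - meanpool(Gs)| computed
from the ground truth with a 31-pixel mean-pool neighbourhood (alpha = 1,
beta = 5), so pixels near the boundary weigh up to six times more than flat
regions. The absolute value keeps W >= alpha on both sides of the boundary.
The hybrid objective is

L_total = L_edge + (wBCE + wIoU) / 2,

where L_edge is the mean binary cross-entropy between the edge probability
map and the morphological-gradient edge ground truth (computed at the edge
head's stride-4 resolution from the nearest-neighbour-downsampled mask), and
the weighted BCE and weighted IoU act on Ps. With deep supervision (default
on) the same weighted segmentation loss is also applied to the sigmoid of
the upsampled coarse map. The edge term uses a mean reduction so that both
terms are on comparable scales and enter 1:1. Log arguments are clipped at
1e-7.

## Training regime

Adam with initial learning rate 1e-4, decayed by 10% every 30 epochs, batch
size 4, at most 60 epochs with early stopping after 10 epochs without
validation-Dice improvement. Inputs are 96x96 patches; each step draws one of
the scale ratios (0.75, 1, 1.25) and resamples the whole batch (bilinear for
images, nearest-neighbour for masks), so one shared network sees three
scales over the course of training -- scale jitter rather than three
simultaneous forward passes, since a single network processes all scales.
Evaluation always runs at scale 1. Datasets are split 9:1 at patient level;
the held-out patients serve as the validation set for early stopping.
Binarization uses threshold 0.5.

Because the feature levels follow ceil(H/stride) and the decoder realigns
scales by bilinear resampling, the network accepts the 72- and 120-pixel
jittered inputs directly; only the public `extract_features()` contract
requires divisibility by 32.

## Synthetic phantoms

The generator renders star-convex nodules (a disc radially perturbed by a
short random cosine series, amplitudes decaying as 1/j^2 so the area stays
within [0.5, 1.5] of the nominal disc) on a dark parenchyma background
(intensity 0.15) with additive Gaussian noise (sigma = 0.05). Type variants:
juxta-pleural nodules touch a bright wall band, juxta-vascular ones
intersect a bright tube, ground-glass nodules cap the contrast at 0.3,
cavitary nodules carry an interior intensity hole under a filled mask, and
calcified nodules use near-saturating contrast. Around each nodule five
non-centered, non-square crops are taken with at least a 4-pixel margin and
randomized per-side padding, then resized to 96x96. Synthetic patients use
disjoint seed ranges, so the patient-level split also separates generator
state. Everything is bit-reproducible from the configuration seed.

What the phantoms do *not* emulate: CT physics (no HU calibration, beam
hardening or reconstruction kernels; intensities live in [0, 1]), 3-D slice
continuity, and real anatomical clutter. Passing tests on phantoms
demonstrates that the architecture, losses, optimizer and metrics are
implemented correctly and that the network can learn nodule shapes; they say
nothing about clinical performance, which requires real annotated CT data.

## Numerical choices

* The convolutional core (conv2d via im2col+GEMM, batch normalization,
  bilinear resizing, a reverse-mode tape, Adam) is implemented inside the
  package; gradients are verified against central finite differences in the
  test suite.
* Batch normalization always uses batch statistics. Prediction is per-image,
  so evaluation is deterministic and a reloaded checkpoint reproduces the
  validation Dice exactly.
* Bilinear resampling uses half-pixel-centered, border-clamped interpolation
  matrices; constants are preserved exactly, which the cross-scale block
  algebra tests rely on.
* Weight init is He-normal, seeded; the three jitter scales and batch
  shuffling draw from one seeded stream, so training is reproducible on CPU.
* Mean-pooling for the edge-weight map uses symmetric (mirror) padding;
  morphological gradients use replicate padding, so constant masks have
  empty edges.
* Empty-vs-empty mask conventions: DSC = JA = 1; sensitivity is undefined
  (NA) for an empty ground truth and excluded from aggregates, as is HD95
  when either mask is empty. Pixel spacing defaults to 1 (isotropic).
* The S-measure uses the probability map (not the binarized mask), balance
  coefficient 0.5; the E-measure uses a plain mean over pixels of the
  enhanced-alignment term.
* 95% confidence intervals are mean +/- 1.96 sd/sqrt(n) over test images.

## Design decisions that were genuinely open

* The cross-scale aggregation uses levels {3, 4, 5}; the deepest-level
  fixpoint f5'' = f5' makes the recursion well-defined.
* "A set of filters" before the edge fusion is realized as one 1x1
  projection per input plus one 3x3 convolution after the fusion; "Convs" in
  the fusion blocks is two 3x3 conv+ReLU stages and "Conv" one 3x3
  conv+ReLU.
* Edge supervision is applied at fE^'s stride-4 resolution; supervising at
  full resolution would upsample a learned edge map only to compare it with
  an interpolated target.
* The five crop rectangles' positioning and aspect-ratio ranges are exposed
  as configuration (margins per side) rather than fixed constants.
* ImageNet pretraining is an optional weight-loading hook
  (`backbone_config(pretrained_path=)`); a missing file is an error, never a
  silent random init. Random He init is the default so nothing external is
  required.

## Problem sizes used by the test suite

The unit and acceptance tests run a width-1/16 backbone with one bottleneck
per stage. The learning sanity check trains on 16 synthetic 96x96 patches
(4 patients x 4 crops) for at least 150 Adam iterations at learning rate
1e-3 -- the larger step suits a tiny randomly-initialized network, whereas
the 1e-4 default matches the full-width, pretrained regime -- and requires a
mean training Dice of at least 0.85 on two of three seeds. The pipeline
check builds 10 synthetic patients (50 patches), splits 9:1 by patient,
trains two epochs and verifies that the evaluation report populates all
eight metrics.

## A worked example

```{r example, eval = FALSE}
td <- tempfile()
man <- build_dataset(synth_config(n_patients = 10), td)
sp <- split_patients(man, seed = 5)
fit <- fit_model(sp$train, sp$test, data_dir = td,
                 config = train_config(lr0 = 1e-3, max_epochs = 2,
                                       width = 1 / 16, blocks = c(1, 1, 1, 1)))
glance(fit)
preds <- predict_masks(fit, load_patches(sp$test, td)$image)
```

## Known limitations

Strictly 2-D; no DICOM or HU handling; the hand-rolled training core is
CPU-oriented and desk-scale -- reproducing full clinical benchmarks would
require the original datasets and GPU-scale training, which is outside this
package's scope.
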