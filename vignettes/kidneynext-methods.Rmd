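---
title: "KidneyNeXt: model, training protocol, and verification strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KidneyNeXt: model, training protocol, and verification strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

KidneyNeXt is a compact convolutional network for classifying renal CT
slices into diagnostic categories (normal parenchyma, cyst, stone, benign
and malignant masses). Slices arrive as ordinary PNG/JPG exports of any
size and bit depth; they are standardized to 224 × 224 RGB in `[0, 1]`
with bilinear resampling, grayscale replicated across channels, and no
augmentation.

The network has four components.

**Patchify stem.** Two *parallel* convolutions, each 4 × 4 with stride 4
(kernel = stride: non-overlapping patches), each followed by batch
normalization and GELU; their elementwise average is the base feature
map. At 224 × 224 input this produces a 56 × 56 × 96 tensor. The stride
is forced by the published stage geometry (224 → 56); the two branches
are independently parameterized but structurally identical.

**Four-branch blocks.** Each block runs its C-channel input through four
shape-preserving branches — 3 × 3 max pooling, 3 × 3 average pooling
(both stride 1, padding 1), and two independent grouped 3 × 3
convolutions (6 groups, each conv → BN → GELU) — concatenates them to 4C
channels, and compresses back to C with a 1 × 1 convolution (BN + GELU).
An identity shortcut around the block is added to the activated output;
it carries no parameters because the block preserves both shape and
channel count. Pooling stride/padding are chosen so the branch outputs
are concatenable with the convolutional branches, which the published
dimensions require. Average pooling divides by the number of valid
(non-padded) window elements so that constant maps remain constant at
borders.

**Transitions.** Between stages 1–3 a 2 × 2 stride-2 convolution doubles
channels and halves each spatial dimension, followed by batch
normalization. Stage widths are 96/192/384/768 with one block per stage;
the published stage table's final 1 × 1 × 768 entry is read as the
global-average-pooling output rather than as an extra downsampling
inside stage 4, so the pre-pooling feature map is 7 × 7 × 768.

**Head.** Global average pooling collapses the final map to a
768-vector, followed by a fully connected layer and softmax. Ties at the
argmax break to the lowest class index under the (lexicographic) class
order.

With these choices the reference configuration (3 classes) has exactly
7,060,899 trainable parameters — 7.1 M to one decimal — which the test
suite cross-checks against a closed-form layer-by-layer count.

## Initialization

Convolution weights use Kaiming fan-in initialization; batch-norm scale
and shift start at 1/0 with running statistics 0/1; all biases start at
zero. The fully connected head starts at **zero** rather than at random
values: an untrained classifier then outputs exactly uniform
probabilities — an uninformative prior — and training is unimpeded
because the gradient through the pooled features breaks the symmetry
immediately. All initialization is seeded; identical seeds give bitwise
identical parameter arrays.

## Data partitioning

Splitting is stratified per class: 80 % of each class (rounded half-up)
to training, the rest to test; then 30 % of each class's training share
(rounded half-up) is reserved for validation. This per-class arithmetic
reproduces the published train/test inventories of both the three-class
collected dataset and the four-class KAUH dataset exactly, which is how
the rounding convention was fixed. Splitting is at image level (no
patient identifiers exist in the folder layout). One published
inventory for the public four-class Kaggle collection is internally
inconsistent (its per-class train + test totals exceed the stated class
sizes), so the split rule is validated against the other two datasets
only.

## Training protocol

The fine-tuning recipe is: SGD with momentum 0.9, 30 epochs, initial
learning rate 0.01, batch size 128, L2 coefficient 1e-4, reshuffling at
every epoch start, no early stopping and no best-checkpoint restore —
the final-epoch parameters are returned unconditionally. Choices the
recipe leaves open were resolved as follows:

* **Loss** — class cross-entropy on the softmax output (the standard
  choice for a softmax classification head).
* **Schedule** — an "initial" learning rate suggests a schedule but none
  is given; the default holds the rate constant, and an optional step
  hook (`lr_steps`/`lr_decay`) is exposed for runs that need one.
* **L2 scope** — applied to convolution and head weights only, not to
  biases or batch-norm scale/shift, the conventional decoupling.
* **Validation cadence** — once per epoch.
* **Batch-norm** — biased batch statistics in training, exponential
  running averages (momentum 0.1, eps 1e-5) for inference; inference is
  therefore deterministic.

Large-scale pre-training (AdamW, 90 epochs, learning rate 1e-3, weight
decay 1e-4) is represented as a configuration record plus a checkpoint
loading pathway; the run itself is out of scope at desk scale, so models
here start from seeded random initialization.

Deep features for classical classifiers are tapped either at the pooled
768-vector feeding the fully connected layer (default) or at the K
pre-softmax scores; the published phrasing ("features from the final
fully connected layer") is ambiguous between the two, so both are
exposed.

## Metrics

All reported numbers derive from the K × K confusion matrix in fixed
class order. For each class taken one-vs-rest, TP is the diagonal cell,
FN the rest of its row, FP the rest of its column, TN the remainder.
Precision, recall, F1 (harmonic mean) and *per-class* accuracy
(TP + TN)/total are percentages; the *overall* accuracy is
trace/total — the published tables use both, and the two are labeled
distinctly here. Macro averages are unweighted class means. Zero
denominators yield 0 with a degeneracy flag and are excluded from macro
means; no published table contains such a cell, so the convention never
affects comparisons. Values are stored at full precision and displayed
half-up at two decimals, the convention that matches every published
cell (e.g. 4478/4480 → 99.96). One-vs-rest ROC curves sweep the unique
scores (ties collapse into single threshold steps) with trapezoid-rule
AUC, equivalent to concordant-pair counting with half credit for ties.

## Grad-CAM

Saliency maps backpropagate the *pre-softmax* score of the target class
(the cited formulation) to a tapped convolutional map — by default the
final stage's pre-pooling 7 × 7 × 768 tensor, configurable down to
stage 1 — weight each channel by its spatially averaged gradient,
rectify the weighted sum, min–max normalize to `[0, 1]` (an all-zero map
stays zero), and bilinearly upsample to the input size. The target
defaults to the predicted class. Normalization makes the map invariant
to positive rescaling of the gradient, which the tests exercise
directly.

## The phantom generator

Real CT collections cannot ship with the package, so every module is
exercised on seeded CT-like phantoms: a dark background, a brighter
elliptical body, two kidney ellipses, and a class-conditional lesion in
one kidney — benign: well-circumscribed bright disc (~0.90 intensity vs
~0.55 kidney); malignant: larger irregular star-shaped mass (~0.70) with
strong pixel-level heterogeneous texture (sd 0.18); cyst: hypodense disc
(~0.22); stone: small strongly hyperdense focus (~0.95); plus Gaussian
noise (sd 0.02). Geometry and intensities
are free choices calibrated once so the classes are machine-separable
yet visually nontrivial (lesion/kidney contrast well above 0.15), with
benign and malignant kept the closest pair (they differ in size, border
regularity, and homogeneity — the radiological cues — not merely in mean
intensity). Ground-truth lesion masks are emitted alongside for
localization scoring.

What phantoms do *not* model: anatomy beyond two ellipses, Hounsfield
calibration, reconstruction physics, partial-volume effects, scanner
variation, or patient-level correlation between slices. Passing the
phantom-scale tests therefore demonstrates that the architecture,
optimization, metric and saliency machinery are implemented correctly
and can extract the intended class structure — not that the published
accuracies on real CT data are reproduced, which would require the
external datasets and full-scale training.

## Desk-scale verification experiment

The standing experiment used by the test suite: 200 phantoms per class
(benign/malignant/normal) at 96 × 96 — large enough that lesions span
several stem patches — split 80/20 with 30 % validation, and a reduced
network (stage widths 8/16/32/64, 2 groups) trained for 18 epochs with
SGD momentum at learning rate 0.003, batch 16, stepped down ×0.25 at
epochs 12 and 16 (the step hook; the constant-rate default at this tiny
scale converges more slowly and oscillates near the optimum). The run
takes a few minutes on one CPU. Held-out accuracy is required to reach
95 %, and on ≥ 80 % of seeded malignant phantoms the Grad-CAM mean
inside the lesion mask must exceed the mean outside.

## Numerical choices and degenerate inputs

* Convolution, pooling and their gradients are direct dense loops in
  C++; the forward kernels are verified against independent
  brute-force oracles in R, and the entire backward pass against
  central finite differences.
* GELU is exact (`x Φ(x)`), not the tanh approximation.
* Zero-area images, odd spatial sizes at transitions, channel
  mismatches, unknown classes and vocabulary violations all raise
  informative errors rather than producing silent misshapes.
* Bilinear resampling uses half-pixel-centre coordinates clamped at the
  borders; the identity resize returns the input unchanged.
* Images with integer-coded intensities are rescaled by the maximum
  representable value of their apparent bit depth; CT windowing is not
  applied (inputs are assumed pre-windowed exports).

## Known limitations

* No GPU path and no im2col/BLAS convolution: full-scale (224 px,
  96-channel) training is out of reach; the package targets exact
  architecture accounting, protocol fidelity, and desk-scale
  verification.
* JPG decoding is not available in this build; PNG is the supported
  interchange format and JPG files are skipped with a warning.
* Image-level (not patient-level) splitting, matching the folder-layout
  contract.
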