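---
title: "Methods: an inception-augmented U-Net for liver CT segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an inception-augmented U-Net for liver CT segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The segmentation problem

Delineating the liver (and lesions inside it) on axial abdominal CT slices
is a binary semantic-segmentation task: every pixel of a 2-D slice is
classified as organ or background. The liver's shape, border and density
change from slice to slice and from patient to patient, and its contrast
against neighbouring soft tissue is low, which is why plain encoder-decoder
networks benefit from extra multi-scale feature extraction on their skip
connections. `aimunet` implements such an architecture — a U-shaped
encoder-decoder whose four skip connections each pass through a two-stage,
four-branch inception module — together with every surrounding stage needed
to run it end to end on one CPU: synthetic phantoms, preprocessing,
augmentation, training, thresholding, volume assembly and evaluation.

## Architecture

The contracting path has four stages of two 3×3 convolutions (64, 128, 256,
512 filters) each followed by 2×2 max-pooling, and a 1024-filter
bottleneck. The expanding path mirrors it with 2×2 transposed-convolution
upsampling and two 3×3 convolutions per stage. The head is a 1×1
convolution with a sigmoid, emitting one probability per pixel.

Each skip connection carries an **inception module part (IMP)**: two
repetitions of a four-branch block —

* branch 1: 1×1 convolution;
* branch 2: 1×1 reduction, then 5×5 convolution;
* branch 3: 1×1 reduction, then two 3×3 convolutions;
* branch 4: 3×3 max-pool (stride 1), then 1×1 convolution —

whose outputs are concatenated, followed by two closing 3×3 convolutions.
Batch normalisation and ReLU follow every convolution inside the IMP.
All IMP operations are stride-1 with same padding, so spatial dimensions
are preserved. At each level the decoder receives the concatenation of the
encoder features, the IMP output and the upsampled deeper features.

### Calibration of the width hyper-parameters

The published account of this architecture fixes its global totals —
41,695,169 parameters, of which 41,672,129 trainable and 23,040
non-trainable, in 188 layers — and the per-level output widths of a
reference layer table, but not the internal branch widths of the IMPs nor
the exact placement of batch normalisation outside them. Those totals are
strong constraints:

* 23,040 non-trainable parameters mean exactly 11,520 batch-normalised
  channels (two running statistics per channel);
* the total parameter count bounds the IMP convolutions to roughly 7.5 M
  parameters once the U-Net backbone is accounted for;
* 188 graph nodes constrain how many batch-norm, concatenation and
  dropout nodes the graph can contain.

Working through the arithmetic rules out several otherwise-plausible
readings. Reading the reference table's skip-connection widths
(128/256/512/1024) as IMP-internal convolution widths is impossible — a
single 1024-wide 3×3 tail convolution at level 4 alone exceeds the whole
parameter budget — so the table's skip width is read as the *post-concat*
width: encoder features (64/128/256/512) concatenated with an equally wide
IMP output. Batch normalisation restricted to the IMPs, or applied
everywhere, is likewise incompatible with the channel total; placing it on
the IMPs plus the contracting path (encoder and bottleneck) satisfies it.
Within these constraints the remaining freedom — the four branch widths
`b` and reduction widths `r` per level — was resolved by solving the
resulting integer system exactly. The shipped defaults are

| level | encoder width | branch width `b` | reduce width `r` | tail width |
|------:|--------------:|-----------------:|-----------------:|-----------:|
| 1 | 64  | 256 | 8   | 64  |
| 2 | 128 | 160 | 8   | 128 |
| 3 | 256 | 16  | 208 | 256 |
| 4 | 512 | 8   | 128 | 512 |

together with two dropout nodes (end of encoder stage 4 and of the
bottleneck, rate 0 by default: the nodes are part of the graph, dropping is
off) and single three-way skip concatenations. Under the documented
node-counting convention (input, convolution, batch norm, pooling,
upsampling, concatenation, dropout and output nodes count as one layer
each; ReLU/sigmoid activations are attributes of the node that produces
them), this configuration reproduces all four published totals exactly, as
`build_aim_unet(network_config())` verifies at run time. Every width is a
user-facing knob (`imp_spec()`, `network_config()`), so alternative
allocations can be explored without touching package code.

```{r}
library(aimunet)
net <- build_aim_unet(network_config())
net$totals
```

## Preprocessing

The pipeline order is fixed: **window → equalise → resize → normalise**.

* **Hounsfield windowing** clamps raw HU to `[-100, 200]`, the abdominal
  soft-tissue range; air, fat below −100 and bone above 200 saturate.
* **Histogram equalisation** uses a 256-bin quantisation of the windowed
  range and remaps intensities through the normalised cumulative
  histogram. The mapping is monotone, so pixel rank order is never
  inverted; a constant slice stays constant.
* **Resizing** to the 256×256 network input uses bilinear interpolation
  for images and nearest-neighbour for masks (masks remain strictly 0/1).
* **Normalisation** affinely maps the slice's `[min, max]` onto `[0, 1]`;
  constant slices map to zero.

**Augmentation** produces exactly six extra views per training pair —
centre crop (87.5 % then resize back), ±15° rotations, 5×5-cell grid
distortion of magnitude 0.3, vertical flip, and a brightness/contrast
perturbation of up to ±0.2 — so an augmented set is exactly seven times
its source. Geometric transforms are applied with identical parameters to
image (bilinear, zero fill) and mask (nearest-neighbour); photometric
transforms never touch the mask. The magnitudes are package defaults
(`augmentation_policy()`), chosen as moderate values that keep the liver
inside the field of view; only the set of six transform types is fixed.
Augmentation is meant for training pairs only — validation and test pairs
are evaluated unaugmented.

**Patient-level splitting** assigns whole patients: 10 % of patients to
test, then 30 % of the remainder to validation and 70 % to training. No
subject ever contributes slices to two sets; the partition is
deterministic under its seed.

## Training protocol

Adam (moments 0.9/0.999) with learning rate 10⁻³, batch size 3, 100
epochs, binary cross-entropy with predictions clipped to
`[10⁻⁷, 1 − 10⁻⁷]`, a 0.20 within-training validation division, and
thresholded (0.5) Dice/IoU/recall/precision tracked per epoch. Early
stopping on validation loss with patience 5 is available but off by
default. The best-validation-loss weights are retained. Two training-time
choices deserve note:

* Batch-norm running statistics use momentum 0.9, suited to the short
  CPU-scale runs this package targets (with the conventional 0.99 the
  inference-mode statistics lag hundreds of steps behind the batch
  statistics, distorting early-epoch validation metrics).
* The within-training 0.20 validation division and the patient-level
  30 % validation split are distinct mechanisms; the pipeline uses the
  patient-level split when patient identity is known and the 0.20
  fraction otherwise.

The runtime is a purpose-built CPU engine (compiled
convolution/pooling/batch-norm kernels behind an R graph executor) rather
than a GPU framework; it is exact — its gradients are verified against
finite differences in the test suite — but desk-scale: reduced
configurations (base 4–8 filters, 64×64 inputs) train in minutes, while
the full-size network is practical for architecture accounting and
inference-shape checks rather than full training.

## Post-processing and evaluation

Probability maps are thresholded at 0.5 with ties to background (a pixel
equal to 0.5 is background; only values strictly greater are organ).
Thresholding is idempotent. Per-patient masks stack into `(n, h, w)`
volumes exportable as NIfTI; tumour masks can optionally be clipped to the
predicted liver.

Evaluation uses pixel confusion counts: accuracy `(TP+TN)/total`, recall
`TP/(TP+FN)`, precision `TP/(TP+FP)`, Dice `2|P∩G|/(|P|+|G|)`, Jaccard
`|P∩G|/|P∪G|` and Dice loss `1 − DSC`. Degenerate denominators yield a
flagged 0 (or a flagged 1 for Dice/Jaccard on two empty masks, so
liver-free slices do not poison averages). Aggregation reports the
arithmetic mean and *population* standard deviation per metric, formatted
as percentages ("97.86 ± 4.65" style); slice-level and patient-level
aggregation are both available since reports simply row-bind.

A note on the loss formula as conventionally printed: binary cross-entropy
is implemented with the ground truth weighting the logarithm of the
prediction, `−[g log p + (1−g) log(1−p)]`; the variant with the roles
swapped is undefined for binary ground truth.

## The phantom generator

Real CT cohorts are not required for any test: the phantom module emulates
the statistical structure of liver-bearing abdominal slices.

* One bright, convex-ish liver region per slice: an ellipse with semi-axes
  drawn from a configurable range, perturbed by bounded low-frequency
  radial noise (≤ 12 % by default) so connectivity is preserved and the
  pixel area stays within analytic bounds
  (`phantom_area_bounds()`) — which is what makes the generator testable.
* Intensities inside the abdominal window: liver 60 ± 10 HU, hypodense
  tumours at −30 HU offset, background clutter ellipses in the −100…0 HU
  range, additive Gaussian noise of 5 HU.
* Tumours appear with configurable probability (default 0.5), 1–3 disks
  clipped to the liver, so the tumour mask is a subset of the liver mask
  by construction.
* Volumes modulate the liver semi-axes with a smooth axial profile (small
  at the ends, largest mid-volume), emulating the through-plane area
  variation of a real liver stack; per-patient stack lengths are drawn
  from a configurable interval.

Every slice is a deterministic function of `(seed, patient_id,
slice_index)` through a counter-based stream, so any slice is reproducible
in isolation and test order never matters.

What the phantoms do *not* model: multi-organ anatomy, scanner physics
(beam hardening, partial volume), inter-observer label noise, or the
contrast distribution of pathological livers. Passing tests on phantoms
therefore demonstrates that the pipeline's machinery — shapes, masks,
losses, accounting, reproducibility — is correct, not that the shipped
defaults reach clinical accuracy on real cohorts; the published
clinical-scale scores require external datasets and GPU-scale training and
are out of scope here.

## Numerical choices and degenerate inputs

* Mask files binarise on read: any nonzero stored value becomes 1
  (annotation tools commonly store 0/255).
* Slice ordering for DICOM series: ascending slice location, ties broken
  by instance number.
* Coordinates are row-major with origin top-left; slice indices are
  0-based.
* Batch-norm epsilon is 10⁻³; convolution weights use He-normal
  initialisation; biases start at zero.
* Even-kernel "same" padding (the 2×2 upsample-then-conv variant) pads
  more on the trailing edge.
* Constant slices: equalisation and normalisation both have stated
  degenerate rules (constant → constant, constant → zeros).
* The 8-bit image export uses a fixed affine map from HU `[-160, 240]`;
  `image_to_hu()` inverts it so the preprocessing chain sees HU again.

## Problem sizes used by the test-suite experiments

The test suite exercises the overfitting check at the reduced scale the
package documents for desk experiments: base 8 filters, 64×64 phantom
slices, five pairs, at most 300 full-batch Adam steps — it reaches a
training Dice of 0.95 in roughly a hundred steps. The end-to-end smoke
pipeline uses five phantom patients of 4–6 slices at 64×64 with base 4
filters and two epochs, run twice under one seed to confirm bit-level
reproducibility of the evaluation CSV. Architecture accounting always uses
the full-size 256×256 description, which is data-free.

## Known limitations

* The calibrated IMP widths reproduce the published totals exactly but are
  one solution of an under-determined system; other allocations with the
  same totals exist, and `imp_spec()` exposes them.
* The CPU engine is single-threaded and double-precision; it is built for
  correctness and desk-scale experiments, not throughput.
* DICOM support covers uncompressed Explicit-VR little-endian single-frame
  files (the format the package's own fixture writer emits), not the full
  standard.
* Only binary (single-head sigmoid) segmentation is implemented;
  multi-class heads are out of scope.
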