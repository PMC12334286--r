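---
title: "Models and methods behind tumorseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tumorseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorseg)
```

`tumorseg` segments tumors in 2-D MRI slices and converts segmented masks
into physical areas. This vignette explains the models and procedures it
implements, the parameters that matter, the design decisions taken where the
architecture left genuine freedom, and what the desk-scale experiments in the
test suite do and do not demonstrate.

## The segmentation problem

On FLAIR MRI, lower-grade gliomas typically appear as hyperintense regions
inside darker brain tissue. The task is binary pixel labelling: given an
intensity image, produce a mask in which 1 marks tumor. Downstream, the mask
is the quantity of clinical interest — its pixel count, combined with the
physical pixel spacing stored in the scan metadata, yields a tumor area in
mm² that can be tracked over time.

## Classical thresholds

Two classical estimators of a global threshold `T` are provided as
baselines, both applied through the rule "foreground where `f(x,y) >= T`"
(pixels exactly at the threshold are foreground; the same convention is used
inside both estimators, so the rule and its estimators are consistent):

* **isodata**: iterate `T <- (mu1 + mu2)/2` with `mu1`, `mu2` the
  foreground/background means at the current `T`. The iteration starts from
  the global mean (a standard convention; the starting point is an argument)
  and stops when the threshold moves by at most `tolerance`, default 0.5 —
  below the quantization step of 8-bit data, so on such data the stop is
  effectively exact. On 8-bit images the threshold sequence takes finitely
  many values, and a safety cap of 256 iterations is enforced with a
  convergence flag.
* **Otsu**: scan every distinct observed level as a candidate and return the
  one maximizing the between-class variance `w0*w1*(mu1 - mu0)^2`; ties break
  toward the lowest level so the result is deterministic. The implementation
  is validated in the tests against an independent brute-force scan and
  against the identity `total variance = within + between` at every
  candidate (relative error below 1e-9).

A worthwhile caveat the phantoms make visible: a *global* threshold on a
brain slice separates bright tissue from dark background, not lesion from
brain, so its Dice score against the lesion mask is poor. That failure is
the motivation for the learned models.

## Network family

All three networks are 256x256x3 in, 256x256x1 out (any size divisible by 16
works), ending in a 1x1 convolution with a sigmoid producing per-pixel tumor
probabilities. `predict_mask()` binarizes at 0.5 by default.

* **Classic U-Net**: encoder stages of two 3x3 ReLU convolutions at widths
  64/128/256/512 with 2x2 max pooling, a 1024-wide bottleneck, and a
  mirrored decoder of 2x2 transposed convolutions, skip concatenations and
  two 3x3 convolutions per stage. 31,031,745 trainable parameters — 31.0 M
  at three significant figures.
* **VGG19 U-Net**: the 16-convolution VGG19 stack as encoder, with skip
  tap-offs at the last convolution of blocks 1–4 and block 5 as the bridge;
  decoder stages of a 2x2 transposed convolution, skip concatenation and two
  batch-normalized 3x3 convolutions at widths 512/256/128/64. 31,168,193
  trainable and 3,840 non-trainable parameters (the moving statistics of the
  eight decoder batch-norm layers: 2·(2·512+2·256+2·128+2·64)).
* **Proposed lightweight variant**: VGG19 encoder with dropout (rate 0.2 by
  default) after each block, and a decoder built from depthwise-separable
  operations refined by attention, described next. 20,435,481 trainable and
  exactly 2,880 non-trainable parameters under the shipped defaults.

### The separable-convolution unit

The decoder's workhorse is a unit of: depthwise 3x3 convolution (with bias),
pointwise 1x1 convolution (with bias), batch normalization, ReLU. Its
parameter count is `9*Cin + Cin + Cin*Cout + Cout + 2*Cout` trainable plus
`2*Cout` non-trainable moving statistics — e.g. 9,216 + 256 for a 64→128
unit, an order of magnitude below the `9*Cin*Cout + Cout` of a standard
convolution at these widths. The tests verify this closed form against the
built layers for random channel pairs.

### CBAM

The convolutional block attention module refines a feature map in two
sequential, sigmoid-gated steps. *Channel attention*: average- and
max-pooled channel descriptors pass through a shared two-layer bottleneck
(reduction ratio `r`, default 8; biases zero-initialized) and the summed
outputs are squashed into per-channel weights in (0,1). *Spatial attention*:
per-pixel mean and max over channels form a 2-channel map convolved with a
7x7 kernel (depthwise-separable by default; a standard 7x7 two-channel
convolution would carry 99 parameters) into a per-pixel gate. Channel-first
ordering follows the original design of the block. On an all-zero input
every gate is sigmoid(0) = 0.5 by construction, which the tests use as a
fixed point.

### Decoder wiring and the parameter budget

The published complexity figures for this architecture family pin two
numbers for the proposed model: 20.4 M trainable parameters at three
significant figures, and exactly 2,880 non-trainable ones. With the full
VGG19 stack (20,024,384 weights) trainable — forced by the small
non-trainable count, which rules out a frozen encoder — the decoder must fit
within roughly 0.33–0.43 M trainable parameters, and its batch-norm layers
must contribute `2880 = 2*3*(256+128+64+32)` moving statistics: three
batch-normalized separable units per stage at widths 256/128/64/32.

That budget is tight, and it dictated the wiring chosen here. Three
constraints interact: (a) each stage must ingest a VGG19 skip (512 to 64
channels wide), (b) each stage runs three separable units, two of them at
the full stage width, and (c) upsampling is learned (transposed
convolutions). Arithmetic shows the budget cannot accommodate both a wide
transposed-convolution path *and* a wide fusion unit: a decoder whose
transposed convolutions output the stage width and whose first unit consumes
the concatenation spends over 0.46 M on the units alone. The wiring adopted
is therefore:

1. **Narrow carrier upsampling**: a depthwise-separable 2x2 transposed
   convolution (depthwise 2x2 transposed + pointwise, both with bias)
   compresses the deep path to a fixed narrow width (`up_channels`, default
   8) while doubling resolution. The skip connection, not the carrier, is
   the wide information path — the carrier provides coarse localization.
2. **Skip concatenation**, then one separable **fusion unit** mapping the
   concatenation down to the stage width.
3. **CBAM at the stage width**, placed after the fusion unit rather than
   directly on the concatenation: on the concatenation its channel-attention
   bottleneck alone would cost ~150 k parameters at stage 1 and break the
   budget; after fusion it costs ~17 k and gates an already-mixed map.
4. Two further separable units at the stage width.

The bottleneck between encoder and decoder is a pass-through of the block-5
features. A 1x1 sigmoid convolution closes the network. Under these
defaults the decoder lands at ~411 k trainable parameters, total 20,435,481
— printing as 20.4 M — with the non-trainable 2,880 exact. `up_channels`,
the decoder widths, the units per stage and the CBAM hyperparameters are all
configuration, not constants.

FLOPs are reported by `count_parameters()` with a documented convention
(multiply and add counted separately, one forward pass, one output element
per bias/activation/normalization op). Published FLOP figures for
segmentation networks vary by counting tool and convention, so no claim is
attached to this number beyond internal comparability.

### Desk-scale models

`width_multiplier` scales every channel width (floored at one channel), so
the same constructors build faithful miniatures: at 1/8 width the proposed
model has ~324 k parameters and trains on a CPU in minutes. Conv-dominated
layers shrink by the square of the multiplier.

## Training protocol

The defaults encode the reference protocol: soft dice loss
`1 - (2*sum(p*o) + eps)/(sum(p) + sum(o) + eps)` with `eps = 1` (a standard
stabilizer keeping empty-mask batches finite; configurable), Adamax at an
initial learning rate of 2.5e-4, batch size 40, up to 150 epochs, early
stopping once the monitored validation metric fails to improve strictly for
15 consecutive epochs (so a monitor flat from the start stops training at
epoch 16), and restoration of the best monitored epoch's weights. The
monitor defaults to validation accuracy per the protocol; `val_dice` is
offered because accuracy saturates near 1 on class-imbalanced masks and can
fail to distinguish models. Per-epoch history records loss/accuracy/Dice/IoU
on the training batches (with the batch statistics used during the step, as
training-mode metrics conventionally are) and on the validation set in
inference mode.

Batch normalization uses momentum 0.99 for its moving statistics and
epsilon 1e-3; dropout is inverted (activations scaled by 1/(1-rate) during
training). Weights are He-normal initialized with zero biases; every source
of randomness (initialization, shuffling, dropout, phantom generation) is
seeded, and the RNG state of the caller is always restored.

## The autodiff engine

No deep-learning framework is part of the package's dependency set, so the
networks run on a small reverse-mode automatic differentiation engine
implemented in the package: feature maps are `(n*h*w) x C` matrices,
convolutions are implemented as shifted gathers plus BLAS matrix products,
and each operation records a backward closure on a tape. The engine
implements exactly the operations the U-Net family needs. Every gradient —
convolutions, depthwise and transposed variants, pooling, batch
normalization, the attention primitives, and the dice loss — is checked
against central finite differences in the test suite, both per-operation and
end-to-end through a miniature network.

## Synthetic phantoms: what they are and are not

Each phantom is a dark field containing a brighter elliptical "brain" with
smooth sinusoidal texture and, with probability `tumor_probability`, one
rotated elliptical lesion with a Gaussian hyperintensity profile (peak
`tumor_contrast` above the brain base, default 0.4) plus i.i.d. Gaussian
noise (default sd 0.02), clipped to [0,1] and replicated to three channels.
The ground-truth mask is the set of pixels whose *centers* lie inside the
lesion ellipse — membership is analytic, so pixel counts are exact integers
and the area pipeline can be tested for exactness rather than approximate
agreement. Default pixel spacing is 1.0 mm (a typical FLAIR in-plane order
of magnitude; the spacing of any given scan belongs to its metadata, which
is why it is a parameter).

Deliberately absent: MRI physics (bias fields, partial-volume effects,
coil inhomogeneity), multiple or non-elliptical lesions, 3-D structure, and
patient-level correlation between slices. Consequently, passing tests on
phantoms demonstrate *mechanical correctness* — exact areas, consistent
metrics, learnable signal, reproducible pipelines — not clinical
performance. Results on the order of the published full-scale figures (test
Dice ≈ 0.89 on real FLAIR data) require the external patient collection and
GPU-scale training, which are outside this package's scope; the package
encodes the protocol that produced them.

One further caveat carried from the protocol itself: splitting is performed
at slice level (70/15/15 by default, floor rule with the remainder in the
test set). With real multi-slice patients, slice-level splitting leaks
patient anatomy across splits; nothing in the protocol described
patient-level splitting, and the phantom generator has no patient structure,
but users bringing real data should split by patient upstream.

## Numerical and degenerate-input choices

* Min–max normalization of a constant image is degenerate (max = min); it
  returns all zeros with a warning rather than NaN.
* Dice and IoU of two empty masks are defined as 1 (a correct all-negative
  prediction is not penalized); the identity `DSC = 2 IoU/(1+IoU)` holds to
  1e-12 on random masks.
* Trial summaries use the sample (n-1) standard deviation, the usual choice
  for small trial counts such as seven.
* Nearest-neighbour resizing maps target index `i` to source index
  `floor(i * src/dst)`; masks stay strictly binary under every geometric
  transform (arbitrary-angle rotations re-binarize at 0.5), and rotations by
  multiples of 90 degrees are exact pixel permutations. Resizing rescales
  the pixel spacing by `src/dst` per axis so physical areas are preserved up
  to boundary quantization.
* Otsu's candidate set is the distinct observed levels; isodata keeps its
  threshold strictly inside the intensity range so both classes stay
  non-empty.
* Two augmentation schemes are shipped because the protocol describes both:
  fixed rotations (45/90/135 degrees) with flips, and the random
  rotation/shift/zoom scheme (factors 0.2/0.05/0.05, nearest fill) tied to
  training; the random scheme is the default. The rotation factor is
  interpreted as a fraction of 180 degrees and shift/zoom as fractions of
  the image size and of unit zoom, the convention of common augmentation
  layers.

## Desk-scale experiment sizes

The test suite's end-to-end training run uses twenty 64x64 phantoms and the
1/8-width proposed model, trained full-batch for 200 Adamax steps at the
protocol's learning rate — about seven minutes on one CPU. Under that exact
protocol the model is still early in its learning curve (the loss decreases
strictly and Dice rises monotonically, but 200 steps at learning rate
2.5e-4 confine every weight within 0.05 of its initialization, since Adamax
moves each weight by at most the learning rate per step). The same setup
with a learning rate of 0.01 memorizes the twenty phantoms (training
Dice ≈ 0.93) within the same 200 steps, which is the package's evidence that
the architecture, gradients and optimizer are sound; the protocol's own
learning rate simply needs its full-scale step count (~20k steps) rather
than a smoke-scale one.

## Known limitations

Single 2-D slices only (no volumetry across slices); binary masks only (no
tumor grading — area is a size measure, not a grade predictor); pretrained
VGG19 weights are not bundled, so the encoder starts from random
initialization unless weights are supplied; the DICOM reader is a minimal
single-frame, uncompressed little-endian subset for pixel data and pixel
spacing, not a general DICOM implementation; and the pure-R engine is built
for transparency and testability at desk scale, not for GPU-scale
throughput.
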