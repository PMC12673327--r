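---
title: "Classifying knee range of motion from monocular silhouettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying knee range of motion from monocular silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After total knee arthroplasty (TKA), the knee's range of motion (ROM) — the
flexion angle, with 0° a fully straight leg — is the central rehabilitation
endpoint. Clinically it is graded against Knee Society Score thresholds:
flexion is *standard* when the patient can bend to at least 125°, and
extension is *standard* when the leg straightens fully to 0°. `kromnet`
implements an automated grader for single monocular photographs of the
lower limb: the image is reduced to a binary silhouette and a compact
convolutional network maps the silhouette to one of four clinical classes
(standard/substandard flexion, standard/substandard extension, coded 0–3)
or to one of six 25°-wide ROM grades (nominal angles 0°–125°).

Patient photographs of this kind are private, so the package is exercised
end to end on a synthetic silhouette generator that emulates the
acquisition setting: a supine patient's isolated lower limb photographed
side-on.

## Preprocessing

Colour images are converted to grayscale with the ITU-R BT.601 luminance
weights (0.299, 0.587, 0.114), rounded half-up; the conversion in the
original acquisition pipeline is not documented, and BT.601 is the
long-standing default for 8-bit imagery. The grayscale image is then
binarized at the Otsu threshold — the value `t` in `[0, 255]` that
maximizes the between-class variance of the populations `{<= t}` and
`{> t}` over the 256-bin histogram — with pixels **strictly above** the
threshold mapped to `maxval` (default 255) and everything else, including
pixels exactly at the threshold, mapped to 0. Two numerical conventions
are fixed here because they are observable in tests: ties in the variance
scan resolve to the smallest maximizing threshold, and a constant image
returns the constant itself (so strict binarization maps it to all
zeros).

Binarization happens at native resolution; the binary image is then
resized with nearest-neighbour interpolation (which cannot invent gray
values) to the network input side — square, a multiple of 8, default 128
— and scaled to `{0, 1}`. Resizing after binarization rather than before
is a declared convention; the alternative order is not observable from
the published description of the method.

## Network

The classifier is a fixed-shape stack: **six** 3×3 convolution + ReLU
blocks (2×2 max pooling after blocks 1, 2, 4 and 6), **two** dilated
3×3 convolution blocks, **two** squeeze-style channel-attention layers
(one after each dilated block), and **two** fully connected layers closed
by a softmax. Layer *counts* are architectural invariants; widths are
configuration. Two presets ship with the package:

| preset    | conv channels        | dilated | FC hidden | parameters (K=4, 64px) |
|-----------|----------------------|---------|-----------|------------------------|
| `default` | 16-32-32-64-64-128   | 128/128 | 256       | ≈ 1.1 M (128px input)  |
| `small`   | 8-16-16-32-32-64     | 64/64   | 128       | ≈ 0.24 M               |

The published description does not give legible per-layer widths, so the
`default` preset is this package's own convention, and `small` is the
half-width variant used for desk-scale runs throughout the tests and the
acceptance script.

**Dilated convolution.** The two dilated blocks use rates 2 and 4 with
zero padding of `rate × (kernel − 1) / 2`, so spatial resolution is
preserved — the stated motivation for dilation over further pooling — and
the effective kernel extent is `k + (k−1)(rate−1)`. At rate 1 the
operation reduces exactly to standard convolution, which the tests verify
numerically.

**Channel attention.** Each attention layer pools its `C`-channel input
feature map spatially (global average pooling), passes the descriptor
through a bottleneck linear map to `C/16`, a ReLU, an expanding map back
to `C`, and a sigmoid; the resulting per-channel weights in (0, 1)
rescale the feature map channel-by-channel. The reduction ratio 16
follows the `C/16` bottleneck shape of the published equations. Bias
terms are included in both maps: the equations omit them, but
squeeze-and-excitation blocks conventionally carry them.

**Loss.** Training minimizes categorical cross-entropy between one-hot
labels and the softmax outputs. The published objective is written as a
sum over samples; this package reports and minimizes the **mean** over
the batch so that the learning rate is batch-size independent — a
deliberate, documented divergence. Probabilities are clipped at 1e-12
before the logarithm; softmax is computed with the max-subtraction
stabilization so rows sum to 1 even for logits of magnitude 1e4.

The network, its backpropagation and the Adam optimizer are implemented
in vectorized R over BLAS (im2col + GEMM), with the patch gather/scatter
and max-pooling kernels in C++ (Rcpp). Correctness of every gradient is
checked against central finite differences in the test suite.

## Training protocol

Defaults follow the study protocol: batch size 16, learning rate 0.0002,
up to 100 epochs, 8:2 train/test split. The optimizer is not stated in
the protocol; Adam (β₁ = 0.9, β₂ = 0.999) is the de-facto choice at this
learning rate and is the default, with plain SGD available. Splitting is
stratified per class by default (the protocol states only "8:2"); whether
the original split was stratified or patient-grouped is unknown, so both
flags exist and neither is claimed as the original. All randomness —
splitting, initialization, per-epoch shuffling — is derived from explicit
seeds, and a saved model reloads to bit-identical predictions.

## Evaluation

From the K×K confusion matrix (rows = true class) the package derives
per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1, and reports
their **macro** averages (equal class weight — the standard choice under
mild imbalance) alongside micro and support-weighted variants, since the
published tables print single values without naming the averaging mode.
Accuracy is the micro quantity `trace/total × 100`. A class with an empty
denominator contributes 0 to the affected macro average, with a warning.
Channel-attention weight vectors and weight-scaled spatial overlays are
exportable per attention layer for inspection.

## The synthetic generator

Each image is generated from a `limb_pose`: thigh and shank are two thick
segments (capsules) hinged at the knee, so the interior angle at the knee
vertex is `180° − flexion`. The generator emulates, with documented
distributions, the nuisance factors of home photography:

| factor | distribution (128 px canvas) | rationale |
|---|---|---|
| flexion-attempt angle | uniform in [60, 150] | clinically plausible maximal effort |
| extension-attempt angle | uniform in [0, 40] | residual contracture range |
| segment lengths | U[32, 45] px each | adult limb proportions at this framing |
| limb half-width | U[5, 10] px | thigh/shank thickness variation |
| global rotation | U[−10, 10]° | camera not perfectly aligned |
| knee translation | U[−8, 8] px per axis | framing variation |
| background / foreground | 10–80 / gap ≥ 90 intensity | clothing-free limb on plain bedding |
| blur | Gaussian, σ ∈ U[0, 1.2] px | handheld focus/motion |
| noise | additive Gaussian, σ ∈ U[0, 6] | sensor noise |
| occlusion | background rectangle over ≤ 25% of limb pixels, half of images | sub-exclusion clothing overlap |

Canvas sizes other than 128 scale the geometric quantities
proportionally, acting as a resolution knob. The rendering order is fixed
— silhouette → blur → noise → occlusion → clamp to [0, 255] — and every
stochastic stage is seeded from the pose, so identical poses render to
bit-identical PNGs; per-record seeds are derived from the dataset seed
and record index, making datasets order-stable.

Class compositions default to the study's: 300/243/272/288 for the four
classes (1,103 images) and 139/206/219/221/204/165 for the six classes.
The printed six-class counts sum to 1,154, not 1,103; the generator
honours whatever counts are requested and does not attempt to resolve
that discrepancy.

Labelling conventions the source leaves open, decided here once:
"ROM = 0°" for standard extension is applied with a 0.5° tolerance
(an exact zero has measure zero for continuous angles); six-class
membership is nearest-nominal-angle binning with edges at the midpoints
12.5°, 37.5°, 62.5°, 87.5°, 112.5° (an angle exactly on an edge goes to
the upper bin, and angles above 125° belong to the 125° class). Sampled
angles are rounded to 3 decimals *before* labelling so the CSV manifest
is exactly label-consistent.

**What the generator does not emulate:** photorealistic anatomy,
prosthesis outlines, perspective foreshortening, non-uniform
illumination, cluttered backgrounds, or the quality-control rejection
pipeline of real acquisitions. Passing the synthetic end-to-end checks
therefore demonstrates that the pipeline's machinery — preprocessing,
architecture, optimization, evaluation — is correct and that the
thresholded-angle tasks are learnable from silhouettes; it does not
certify clinical performance on patient photographs.

## Verification oracle for the renderer

The test suite validates the renderer's geometry with an estimator that
is independent of the stored joint coordinates: a two-capsule silhouette
model is fitted directly to the binary mask by multi-start Nelder–Mead on
a soft-edge rasterization surrogate, annealing the edge ramp from 4 px
down to 0.25 px, with dedicated starts for strongly folded limbs whose
silhouettes merge into a single blob. The fitted knee angle agrees with
the generative angle within 1° on all 100 noiseless test poses spanning
0–150°.

## Problem sizes and numerical choices

Desk-scale runs in the tests and the acceptance script use the `small`
preset at 64×64 input with 15 epochs (four-class) and 20 epochs
(six-class) on the full study compositions; both tasks exceed 90% / 85%
test accuracy well before those points, and the sizes keep a complete
suite run comfortable on a single CPU. The 16-image memorization check
uses the `default` preset at the native 128×128 input, where 20 epochs at
the study's batch 16 / learning rate 0.0002 drive the training loss below
0.01. Max-pooling ties resolve to the first element in window scan order;
Otsu ties to the smallest threshold; He initialization is used for all
weight matrices with zero biases. Degenerate inputs are rejected loudly:
empty images, out-of-range labels or thresholds, limbs leaving the
canvas (never silently cropped), and non-finite losses abort with
diagnostics.

## Known limitations

* Continuous-angle regression is out of scope; the package classifies
  against fixed thresholds.
* The network is CPU-oriented; there is no GPU path.
* The synthetic benchmark bounds what can be claimed about real
  photographs (see above); no pretrained weights are shipped.
* Reported accuracies on synthetic data depend on the generator's
  nuisance levels, which are fixed package-wide rather than tuned
  per experiment.
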