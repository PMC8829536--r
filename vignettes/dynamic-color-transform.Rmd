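---
title: "Dynamic color transforms for illumination-robust detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic color transforms for illumination-robust detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dctdetect)
```

## The problem

Field phenotyping imagery — wheat head patches being the motivating case —
is collected by many institutions with different cameras, platforms and
lighting. Each acquisition campaign forms a *domain*: a consistent set of
images taken under one set of conditions. Detectors trained on such data
degrade sharply on domains whose illumination differs from the training
distribution, and a large part of that degradation is explained by a very
low-dimensional nuisance: a global gain/offset shift of all intensities.

The dynamic color transform (DCT) attacks exactly that nuisance. A small
network looks at the input image and predicts a single gain `alpha` and
offset `beta`, applied identically to all three channels:

$$x' = \alpha \, x + \beta$$

before the image reaches the detector. Because the parameters are
predicted *from the image*, the correction adapts per input: a dark domain
gets `alpha > 1`, a washed-out one `alpha < 1`. Unifying the three channel
gains into one `alpha` (and likewise `beta`) is deliberate — the transform
corrects illumination, it is not a color remap.

## Two parameter heads

The network body is an encoder, global average pooling, and one
fully-connected head. Two output parameterizations are provided:

* **Regression**: two unbounded outputs are squashed,
  $\alpha = \alpha_{max}\,\sigma(\alpha_x)$ and
  $\beta = \beta_{max}\,\tfrac{2}{\pi}\arctan(\beta_x)$, giving open
  ranges $(0, \alpha_{max})$ and $(-\beta_{max}, \beta_{max})$. Defaults
  $\alpha_{max}=2$, $\beta_{max}=0.1$. We scale the arctan by $2/\pi$ so
  the emitted offset actually spans the stated $(-\beta_{max},
  \beta_{max})$ range; a $1/\pi$ scaling would silently halve it. In
  double precision the sigmoid saturates to exactly 0 or 1 for
  pre-activations beyond about $\pm 37$, so the implementation clamps the
  squashed value to $[10^{-12}, 1-10^{-12}]$; the open range then holds
  for every finite input.
* **Classification**: the parameter values are restricted to grids
  $V_\alpha = \{i_\alpha k\}_{k=1}^{k_{max}}$ and
  $V_\beta = \{i_\beta j\}_{j=-j_{max}}^{j_{max}}$ (the zero level is
  always present, so $V_\beta$ has $2 j_{max}+1$ elements), the head emits
  a softmax distribution per grid, and the emitted parameter is the
  expectation under it. Defaults $i_\alpha = 0.1$, $k_{max} = 20$,
  $i_\beta = 0.1$, $j_{max} = 2$: value ranges $[0.1, 2]$ and
  $[-0.2, 0.2]$. Expectations are convex combinations, so the ranges are
  guaranteed by construction.

```{r heads}
regression_transform_params(regression_head_output(0, 0))     # alpha 1, beta 0
build_beta_values(0.1, 2)
classification_transform_params(
  classification_head_output(c(rep(0, 19), 1), c(0, 0, 1, 0, 0)))
```

## Encoders and parameter accounting

Five encoders are available: canonical ResNet18/34, MobileNetV2 and
ShuffleNetV2 (1.0x) feature extractors (standard stage layouts, truncated
before their classifiers, randomly initialized — no pretrained weights are
downloaded), plus a tiny `toy_linear` encoder (pixelwise linear map to 8
channels, ReLU, pooling) used for fast deterministic tests and desk-scale
training. `count_parameters()` sums every trainable scalar, including the
affine pairs of the normalization layers. With the regression head this
reproduces the published sizes of the canonical extractors — 11.2 M
(ResNet18), 2.2 M (MobileNetV2), 21.3 M (ResNet34); a head contributes
exactly $2C + 2$ scalars over a $C$-channel encoder. The classification
variant of the head is a single fully-connected layer here; architectures
with an extra intermediate layer would count slightly higher.

The layer stack (im2col convolutions, batch-norm affines, pooling) is
implemented in plain R matrix code. Networks built with the same seed are
bit-identical; inference is pure.

## The detector contract and the toy detector

The transform is detector-agnostic: anything implementing
`detect(detector, image, ...)` (or any plain `function(image)`) that
returns a detection tibble can be trained against, ensembled and
evaluated. The bundled `toy_detector()` is a deliberately minimal dense
single-scale detector that honors the standard dense-head contract:

* the image is divided into `stride × stride` cells (stride 16 by
  default); each cell yields a 12-dimensional block-mean intensity
  feature, processed by a one-hidden-layer perceptron into an objectness
  logit and four box offsets;
* a cell is *positive* when a ground-truth box center falls inside it
  (smallest box wins ties); unassigned cells contribute no localization
  loss;
* the loss is binary cross-entropy on objectness plus the mean of
  $1 - GIoU$ over positive cells, where
  $GIoU = IoU - (|C| - |A \cup B|)/|C|$ with $C$ the smallest enclosing
  box.

Gradients are hand-derived; the GIoU term inside the gradient uses central
finite differences on the four decoded coordinates (the decode is smooth
and bounded, so a fixed step of $10^{-4}$ is safe). Both gradient paths
are validated against numerical differentiation in the test suite. The
cell features are *linear* in the pixels, which makes the gradient of the
loss with respect to the input image exact — that is the hook the
transform training uses.

This detector is scaffolding: it is what makes the full pipeline
trainable on a CPU in seconds, not a competitive detector.

## Two-step training

`train_detector()` then `train_dct()` implement the two-step strategy:

1. train the detector (SGD, momentum 0.9, cosine-annealed learning rate
   from 0.1, flips on by default, optional scale and brightness/contrast
   jitter);
2. freeze it (`freeze_detector()`, enforced by contract and verified
   bit-for-bit), and train the transform network by backpropagating the
   same detection loss through the transformed image
   $x' = \alpha x + \beta$ into the DCT parameters only. The transform is
   applied *without clipping* during training so the map stays linear;
   clipping is for export and visualization. The transform is trained
   with flips only — geometric jitter does not interact with a global
   color map, while brightness jitter would corrupt the very signal the
   network must read.

The DCT schedule follows the standard recipe: 50 epochs at learning rate
0.02, divided by ten every 20 epochs. Gradient training is implemented
for the `toy_linear` encoder (both formulations); the convolutional
encoders support inference and parameter accounting, which is what the
desk-scale experiments need.

## Synthetic multi-domain benchmark

`generate_scene()` renders textured canopy-like backgrounds with brighter
elliptical "head" objects and returns each object's tight axis-aligned
box; `generate_benchmark()` builds several domains, each degraded by a
known global linear illumination map $x_{obs} = a\,x + b$ (clipped by
default — real sensors saturate, so exact inversion is impossible and the
correction problem is honest). Desk-scale defaults: 128 px frames, 5–12
objects of 10–22 px — an order of magnitude below real phenotyping
patches, sized so the full two-step pipeline runs in minutes on one CPU.

What the generator emulates: objects separable from background partly by
intensity/color, and domains differing by a global linear illumination
shift with known parameters. What it does not emulate: occlusion, motion
blur, perspective, rotated/elongated heads, within-domain illumination
gradients, or object appearance drift across growth stages. Passing
end-to-end tests therefore demonstrates that the machinery recovers
global linear illumination shifts around a detector — not field-ready
wheat detection.

A typical desk-scale run (3 domains with gains $a \in \{0.6, 1.0, 1.5\}$,
zero offsets, 20 images per domain, detector trained on clean imagery)
behaves exactly as the method predicts: the clean-trained detector
collapses on the darkened domain, a static gain sweep peaks near
$\alpha \approx 1/a$, and the trained dynamic transform recovers most of
the lost accuracy while predicting $\hat\alpha$ near $1/a$ on the dark
domain and near 1 on the clean one. The acceptance suite runs this
experiment over three seeds.

## Evaluation: Average Domain Accuracy

Per image, predictions are matched to ground truth greedily in descending
confidence at IoU strictly above 0.5 (one-to-one), and

$$Accuracy = \frac{TP}{TP + FN + FP}.$$

Images are averaged within their domain and domains averaged across —
every acquisition condition counts equally regardless of image volume. An
image with no objects and no predictions scores 1 (nothing to find,
nothing hallucinated); the formula's 0/0 case is undefined otherwise.
Ties between equal-confidence predictions are broken by input order.

## Ensembling

`tta_predict()` runs a detector on flipped/rotated copies of an image and
maps all boxes back to original coordinates; `vme_fuse()` merges the $K$
resulting prediction sets by majority voting: boxes are clustered
greedily (most confident unassigned box seeds a cluster; it absorbs at
most one box per source with IoU above $\tau = 0.6$), a cluster survives
only with strictly more than $\lfloor K/2 \rfloor$ members (the seed
counts itself — with $K = 3$, two agreeing models suffice and a lone box
dies), and survivors are averaged coordinate-wise and confidence-wise.
With $K = 1$ everything passes through, so single-model pipelines are
unaffected. An exhaustive loop-based oracle (`vme_fuse_oracle()`)
restates the rule independently and the suite checks equivalence on a
thousand random instances. Averaging (rather than max-pooling) the
confidence is a choice; so is forbidding two boxes of the same model in
one cluster.

## Numerical and degenerate-input choices

* Boxes are continuous, 0-based, closed pixel intervals;
  area $= (x_{max}-x_{min})(y_{max}-y_{min})$; degenerate boxes are
  rejected.
* Probability vectors must sum to 1 within $10^{-6}$.
* Degenerate head grids ($k_{max}=1$, $j_{max}=0$) are legal and yield
  constant transforms.
* The box-size decode is bounded to $[e^{-1.4}, e^{1.4}]$ stride
  multiples, so finite-difference steps cannot blow up.
* Detector training at batch size 4; histories record per-step class and
  localization losses; every run is reproducible from its seed.

## Limitations

The global transform cannot help when objects and background share
colors, when degradations are spatially varying, or when the shift is
nonlinear (gamma, saturation); the classification head's published
parameter counts suggest an extra head layer whose exact topology is not
reproduced here; and the bundled detector is intentionally too simple to
transfer to real imagery — swap in a real detector through the
`detect()` contract for that.
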