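# dctdetect

Illumination-robust object detection for plant phenotyping imagery via a
**dynamic color transform (DCT)**: a small network looks at each input
image and predicts one global gain/offset pair `(alpha, beta)`, applied
identically to all three color channels,

```
x' = alpha * x + beta
```

before the image reaches a detector. Field images of wheat heads (and
similar canopy imagery) are collected under wildly different illumination
across acquisition campaigns ("domains"); much of the resulting accuracy
loss is explained by exactly this kind of global linear intensity shift,
and an input-conditioned correction recovers it without touching the
detector.

The package provides, end to end and without any external data:

* the linear color transform and **two parameter heads** — a regression
  head, `alpha = alpha_max * sigmoid(a)`,
  `beta = beta_max * (2/pi) * arctan(b)` with ranges `(0, 2)` and
  `(-0.1, 0.1)` at the defaults, and a classification head that predicts
  a softmax distribution over discrete value grids
  `V_alpha = {0.1, 0.2, ..., 2.0}`, `V_beta = {-0.2, ..., 0.2}` and emits
  the expectation;
* **DCT networks** (encoder → global average pooling → fully-connected
  head) on canonical ResNet18/34, MobileNetV2 and ShuffleNetV2 feature
  extractors plus a tiny `toy_linear` encoder, with exact trainable
  parameter accounting (11.2 M / 21.3 M / 2.2 M for the first three with
  the regression head);
* a **pluggable detector contract** (`detect()`) with a minimal dense
  grid detector, IoU/GIoU geometry, and the standard objectness
  cross-entropy + `1 - GIoU` loss;
* the **two-step training procedure**: train the detector, freeze it,
  then backpropagate its loss through the transformed image into the DCT
  network only;
* **voting-based model ensembling (VME)** of prediction sets with
  test-time augmentation (flips, 90° rotations), majority-vote cluster
  keeping and member averaging;
* the **Average Domain Accuracy (ADA)** metric: per image
  `TP / (TP + FN + FP)` at IoU > 0.5, averaged within and then across
  domains;
* a **synthetic multi-domain benchmark generator** — textured scenes with
  elliptical "head" objects and known per-domain linear illumination
  degradations `x_obs = a * x + b` — so every stage is testable on a CPU
  in minutes.

Everything is tidyverse-shaped: datasets are tibbles with list-columns,
results come back as tibbles or objects with `tidy()` / `glance()` /
`autoplot()` methods, and a thin command-line interface
(`inst/cli/dctdetect`) wraps the same functions.

## Worked example

Three synthetic domains share the same scene statistics but differ by a
global illumination gain (`a` = 0.6, 1.0, 1.5). A detector trained on
clean imagery collapses on the shifted domains; a regression DCT trained
through the frozen detector recovers most of the loss.

```r
library(dctdetect)

domains <- list(
  list(config = scene_config(), degradation = degradation_params(0.6, 0, "dark")),
  list(config = scene_config(), degradation = degradation_params(1.0, 0, "clean")),
  list(config = scene_config(), degradation = degradation_params(1.5, 0, "bright")))
bench <- generate_benchmark(domains, images_per_domain = 20, seed = 1)
train <- subset(bench, split == "train")
test  <- subset(bench, split == "test")

# step 1: detector on clean imagery, then frozen
clean_train <- train
clean_train$image <- clean_train$clean
det <- freeze_detector(
  train_detector(clean_train, train_config(epochs_detector = 30, seed = 1))$model)

evaluate_detector(det, test)
#> <eval_report> ADA = 0.3281 over 3 domain(s), 12 image(s)
#>   domain accuracy n_images
#> 1 bright    0.211        4
#> 2 clean     0.773        4
#> 3 dark      0            4

# step 2: color-transform network through the frozen detector
dct <- build_dct_network("toy_linear", "regression", seed = 1)
fit <- train_dct(train, det, dct, train_config(epochs_dct = 50, seed = 1))

evaluate_detector(det, test, transform = fit$network)
#> <eval_report> ADA = 0.5940 over 3 domain(s), 12 image(s)
#>   domain accuracy n_images
#> 1 bright    0.651        4
#> 2 clean     0.756        4
#> 3 dark      0.375        4
```

ADA rises from 0.33 to 0.59 because the network has learned an
*input-conditioned* correction — it brightens the dark domain and leaves
the clean one nearly untouched (the ideal gain on the dark domain is
`1/0.6 ≈ 1.67`):

```r
predict_params(fit$network, test$image[[which(test$domain == "dark")[1]]])
#> <transform_params> alpha = 1.37243, beta = 0.0275404
predict_params(fit$network, test$image[[which(test$domain == "clean")[1]]])
#> <transform_params> alpha = 1.03684, beta = 0.00867527
```

A static sweep (`color_sweep()`) over fixed `(alpha, beta)` grids shows
the same structure from the outside: on the dark domain the accuracy
maximum sits at `alpha > 1`, far from the identity point. `autoplot()`
renders sweep tables, evaluation reports and training histories;
`plot_scene()` overlays boxes on images.

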