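# Shared fixtures: small synthetic scenes and a cached trained detector so
# several test files can reuse one training run.

fixture_cache <- new.env(parent = emptyenv())

flat_image <- function(h = 8, w = 8, value = 0.5) {
  array(value, dim = c(h, w, 3))
}

small_scene_config <- function() {
  scene_config(height = 64, width = 64, n_min = 3, n_max = 6,
               axis_min = 4, axis_max = 8)
}

# A tibble dataset of synthetic scenes, optionally degraded and labeled.
scene_dataset <- function(seeds, domain = NULL, deg = NULL,
                          config = scene_config()) {
  scenes <- lapply(seeds, function(i) generate_scene(config, seed = i))
  out <- tibble::tibble(image = lapply(scenes, `[[`, "image"),
                        boxes = lapply(scenes, `[[`, "boxes"))
  if (!is.null(deg)) {
    out$image <- lapply(out$image, apply_degradation, deg = deg)
  }
  if (!is.null(domain)) out$domain <- domain
  out
}

# Detector trained once on clean full-size scenes; reused across files.
fixture_detector <- function() {
  if (is.null(fixture_cache$detector)) {
    ds <- scene_dataset(1:30)
    fit <- train_detector(ds, train_config(epochs_detector = 25, seed = 7))
    fixture_cache$detector <- fit$model
  }
  fixture_cache$detector
}

random_boxes <- function(n, frame = 100, min_size = 2, max_size = 20) {
  x <- stats::runif(n, 0, frame - max_size)
  y <- stats::runif(n, 0, frame - max_size)
  w <- stats::runif(n, min_size, max_size)
  h <- stats::runif(n, min_size, max_size)
  tibble::tibble(x_min = x, y_min = y, x_max = x + w, y_max = y + h)
}

random_prediction_sets <- function(k, max_boxes = 15, frame = 100) {
  lapply(seq_len(k), function(i) {
    n <- sample(0:max_boxes, 1)
    b <- random_boxes(n, frame)
    b$confidence <- stats::runif(n)
    b$class_label <- 0L
    prediction_set(i, b)
  })
}
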