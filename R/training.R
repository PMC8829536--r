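#' Training configuration
#'
#' Bundles the hyperparameters of the two-step training procedure: the
#' detector is trained first, then frozen, and the color-transform network
#' is trained through it. Defaults are desk-scale (tens of epochs on small
#' synthetic scenes); the full-scale schedule of the original setting
#' (300 detector epochs with cosine annealing from 0.1; 50 transform epochs
#' at 0.02 decayed tenfold every 20 epochs) is expressible through the same
#' fields.
#'
#' @param epochs_detector,epochs_dct Number of passes over the dataset.
#' @param lr_detector,lr_dct Initial learning rates.
#' @param lr_schedule_detector `"cosine"` (annealed to 0) or `"step"`.
#' @param lr_schedule_dct `"step"` (divided by 10 every `lr_step_every`
#'   epochs) or `"cosine"`.
#' @param lr_step_every Epoch interval of the step decay.
#' @param batch_size Images per gradient step.
#' @param momentum SGD momentum coefficient.
#' @param augment_flip,augment_scale,augment_color_jitter Augmentation
#'   switches for detector training (horizontal/vertical flips, uniform
#'   scale jitter, brightness/contrast jitter). The transform network is
#'   trained with flips only.
#' @param seed Integer seed; recorded in training histories.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs_detector = 20L, epochs_dct = 10L,
                         lr_detector = 0.1, lr_dct = 0.02,
                         lr_schedule_detector = c("cosine", "step"),
                         lr_schedule_dct = c("step", "cosine"),
                         lr_step_every = 20L,
                         batch_size = 4L, momentum = 0.9,
                         augment_flip = TRUE, augment_scale = FALSE,
                         augment_color_jitter = FALSE, seed = 0L) {
  abort_if(!is_number(epochs_detector) || epochs_detector < 1 ||
             !is_number(epochs_dct) || epochs_dct < 1,
           "epoch counts must be positive", class = "dctdetect_validation_error")
  abort_if(!is_number(lr_detector) || lr_detector <= 0 ||
             !is_number(lr_dct) || lr_dct <= 0,
           "learning rates must be positive", class = "dctdetect_validation_error")
  structure(list(epochs_detector = as.integer(epochs_detector),
                 epochs_dct = as.integer(epochs_dct),
                 lr_detector = lr_detector, lr_dct = lr_dct,
                 lr_schedule_detector = match.arg(lr_schedule_detector),
                 lr_schedule_dct = match.arg(lr_schedule_dct),
                 lr_step_every = as.integer(lr_step_every),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 augment_flip = isTRUE(augment_flip),
                 augment_scale = isTRUE(augment_scale),
                 augment_color_jitter = isTRUE(augment_color_jitter),
                 seed = as.integer(seed)),
            class = "train_config")
}

validate_dataset <- function(dataset, arg = "dataset") {
  abort_if(!is.data.frame(dataset) || nrow(dataset) == 0,
           paste0("`", arg, "` must be a non-empty data frame"),
           class = "dctdetect_validation_error")
  abort_if(!all(c("image", "boxes") %in% names(dataset)),
           paste0("`", arg, "` needs list-columns `image` and `boxes`"),
           class = "dctdetect_validation_error")
  invisible(dataset)
}

lr_at <- function(base, schedule, epoch, total_epochs, step_every) {
  switch(schedule,
         cosine = base * 0.5 * (1 + cos(pi * (epoch - 1) / total_epochs)),
         step = base * 10^(-((epoch - 1) %/% step_every)))
}

# --- augmentations ---------------------------------------------------------

flip_image <- function(image, horizontal = TRUE) {
  if (horizontal) image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  else image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
}

flip_boxes <- function(boxes, img_dim, horizontal = TRUE) {
  if (nrow(boxes) == 0) return(boxes)
  out <- boxes
  if (horizontal) {
    w <- img_dim[2]
    out$x_min <- w - boxes$x_max
    out$x_max <- w - boxes$x_min
  } else {
    h <- img_dim[1]
    out$y_min <- h - boxes$y_max
    out$y_max <- h - boxes$y_min
  }
  out
}

resize_nearest <- function(image, new_h, new_w) {
  d <- dim(image)
  rows <- pmin(d[1], floor((seq_len(new_h) - 0.5) * d[1] / new_h) + 1L)
  cols <- pmin(d[2], floor((seq_len(new_w) - 0.5) * d[2] / new_w) + 1L)
  image[rows, cols, , drop = FALSE]
}

augment_sample <- function(image, boxes, config) {
  d <- dim(image)
  if (config$augment_scale) {
    f <- stats::runif(1, 0.8, 1.25)
    nh <- max(32L, round(d[1] * f))
    nw <- max(32L, round(d[2] * f))
    if (nrow(boxes) > 0) {
      boxes$x_min <- boxes$x_min * nw / d[2]
      boxes$x_max <- boxes$x_max * nw / d[2]
      boxes$y_min <- boxes$y_min * nh / d[1]
      boxes$y_max <- boxes$y_max * nh / d[1]
    }
    image <- resize_nearest(image, nh, nw)
    d <- dim(image)
  }
  if (config$augment_flip) {
    if (stats::runif(1) < 0.5) {
      image <- flip_image(image, TRUE)
      boxes <- flip_boxes(boxes, d, TRUE)
    }
    if (stats::runif(1) < 0.5) {
      image <- flip_image(image, FALSE)
      boxes <- flip_boxes(boxes, d, FALSE)
    }
  }
  if (config$augment_color_jitter) {
    gain <- stats::runif(1, 0.85, 1.15)
    offset <- stats::runif(1, -0.05, 0.05)
    image <- pmin(pmax(gain * image + offset, 0), 1)
  }
  list(image = image, boxes = boxes)
}

# --- detector training -----------------------------------------------------

#' Train the grid detector
#'
#' Minimizes the summed objectness cross-entropy and GIoU localization loss
#' with minibatch SGD (momentum 0.9). Images enter normalized to `[0, 1]`.
#' Reproducible given `config$seed`.
#'
#' @param dataset Data frame with list-columns `image` (H x W x 3 arrays)
#'   and `boxes` (data frames of ground-truth boxes).
#' @param config A [train_config()].
#' @param detector Optional initial [toy_detector()]; by default one is
#'   created with the config seed.
#' @return A `detector_fit` with elements `model` and `history`
#'   (a tibble of per-step losses); [generics::tidy()] returns the history,
#'   [generics::glance()] a one-row summary.
#' @export
train_detector <- function(dataset, config = train_config(), detector = NULL) {
  validate_dataset(dataset)
  abort_if(!inherits(config, "train_config"),
           "`config` must be a train_config", class = "dctdetect_validation_error")
  model <- detector %||% toy_detector(seed = config$seed)
  withr::with_seed(config$seed + 1L, {
    vel <- lapply(model$params, function(p) p * 0)
    hist <- list()
    step <- 0L
    n <- nrow(dataset)
    for (epoch in seq_len(config$epochs_detector)) {
      lr <- lr_at(config$lr_detector, config$lr_schedule_detector, epoch,
                  config$epochs_detector, config$lr_step_every)
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      for (batch in batches) {
        acc <- NULL
        lcls <- 0; lloc <- 0
        for (i in batch) {
          aug <- augment_sample(dataset$image[[i]], dataset$boxes[[i]], config)
          res <- detector_loss_grad(model, aug$image, aug$boxes)
          lcls <- lcls + res$loss_cls / length(batch)
          lloc <- lloc + res$loss_loc / length(batch)
          if (is.null(acc)) {
            acc <- lapply(res$grads, function(g) g / length(batch))
          } else {
            acc <- Map(function(a, g) a + g / length(batch), acc, res$grads)
          }
        }
        for (nm in names(model$params)) {
          vel[[nm]] <- config$momentum * vel[[nm]] - lr * acc[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
        step <- step + 1L
        hist[[step]] <- c(step = step, epoch = epoch,
                          loss_cls = lcls, loss_loc = lloc)
      }
    }
    history <- tibble::as_tibble(do.call(rbind, hist))
    structure(list(model = model, history = history, config = config),
              class = "detector_fit")
  })
}

#' Freeze a detector
#'
#' Marks a detector as frozen so it can be passed to [train_dct()], which
#' refuses unfrozen detectors and guarantees the frozen parameters are
#' untouched by transform training.
#'
#' @param detector A detector model.
#' @return The detector, flagged as frozen.
#' @export
freeze_detector <- function(detector) {
  detector$frozen <- TRUE
  detector
}

# --- DCT training through a frozen detector --------------------------------

# Forward pass of the toy_linear DCT with intermediates kept for the
# hand-derived backward pass. X is the npix x 3 pixel matrix.
dct_toy_forward <- function(network, image) {
  conv <- network$encoder$children[[1]]
  x_mat <- matrix(image, ncol = 3)
  z <- sweep(x_mat %*% conv$params$weight, 2, conv$params$bias, "+")
  mask <- z > 0
  pooled <- colMeans(z * mask)
  logits <- as.vector(pooled %*% network$head$params$weight) +
    network$head$params$bias
  list(x_mat = x_mat, mask = mask, pooled = pooled, logits = logits)
}

# Map logits to (alpha, beta) plus d(alpha)/d(logits), d(beta)/d(logits).
dct_params_and_jacobian <- function(network, logits) {
  if (network$formulation == "regression") {
    cfg <- network$head_config
    sa <- stats::plogis(logits[1])
    alpha <- cfg$alpha_max * sa
    beta <- cfg$beta_max * (2 / pi) * atan(logits[2])
    d_alpha <- c(cfg$alpha_max * sa * (1 - sa), 0)
    d_beta <- c(0, cfg$beta_max * (2 / pi) / (1 + logits[2]^2))
  } else {
    cfg <- network$head_config
    k_max <- cfg$k_max
    va <- build_alpha_values(cfg$i_alpha, cfg$k_max)
    vb <- build_beta_values(cfg$i_beta, cfg$j_max)
    ia <- seq_len(k_max)
    pa <- softmax(logits[ia]); pb <- softmax(logits[-ia])
    alpha <- sum(va * pa); beta <- sum(vb * pb)
    d_alpha <- c(pa * (va - alpha), numeric(length(pb)))
    d_beta <- c(numeric(k_max), pb * (vb - beta))
  }
  list(alpha = alpha, beta = beta, d_alpha = d_alpha, d_beta = d_beta)
}

#' Train the color-transform network through a frozen detector
#'
#' The second step of the two-step strategy: the detector's parameters stay
#' fixed while the detection loss, evaluated on the transformed image
#' `x' = alpha * x + beta`, is backpropagated through the transform into
#' the DCT network only. Supports the `toy_linear` encoder (both
#' formulations); the transform is applied without clipping during training
#' so the map stays linear.
#'
#' @param dataset Data frame with list-columns `image` and `boxes`; images
#'   are the (possibly degraded) inputs the transform must correct.
#' @param frozen_detector A detector passed through [freeze_detector()].
#' @param dct A `dct_network` with the `toy_linear` encoder.
#' @param config A [train_config()]; uses `epochs_dct`, `lr_dct`,
#'   `lr_schedule_dct` and flips-only augmentation.
#' @return A `dct_fit` with elements `network`, `history`, and the frozen
#'   detector it was trained against.
#' @export
train_dct <- function(dataset, frozen_detector, dct, config = train_config()) {
  validate_dataset(dataset)
  abort_if(!isTRUE(frozen_detector$frozen),
           "`frozen_detector` must be frozen with freeze_detector()",
           class = "dctdetect_contract_error")
  abort_if(!inherits(dct, "dct_network"),
           "`dct` must be a dct_network", class = "dctdetect_validation_error")
  abort_if(dct$spec$family != "toy_linear",
           "gradient training is implemented for the toy_linear encoder",
           class = "dctdetect_config_error")
  detector_before <- frozen_detector$params
  conv_nm <- 1L  # toy_linear encoder: single conv child
  withr::with_seed(config$seed + 2L, {
    params <- list(enc_w = dct$encoder$children[[conv_nm]]$params$weight,
                   enc_b = dct$encoder$children[[conv_nm]]$params$bias,
                   head_w = dct$head$params$weight,
                   head_b = dct$head$params$bias)
    vel <- lapply(params, function(p) p * 0)
    hist <- list()
    step <- 0L
    n <- nrow(dataset)
    flip_cfg <- list(augment_scale = FALSE, augment_flip = config$augment_flip,
                     augment_color_jitter = FALSE)
    for (epoch in seq_len(config$epochs_dct)) {
      lr <- lr_at(config$lr_dct, config$lr_schedule_dct, epoch,
                  config$epochs_dct, config$lr_step_every)
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      for (batch in batches) {
        acc <- lapply(params, function(p) p * 0)
        lcls <- 0; lloc <- 0; alpha_bar <- 0
        for (i in batch) {
          aug <- augment_sample(dataset$image[[i]], dataset$boxes[[i]], flip_cfg)
          res <- dct_grad_step(params, dct, frozen_detector,
                               aug$image, aug$boxes)
          lcls <- lcls + res$loss_cls / length(batch)
          lloc <- lloc + res$loss_loc / length(batch)
          alpha_bar <- alpha_bar + res$alpha / length(batch)
          acc <- Map(function(a, gg) a + gg / length(batch), acc, res$grads)
        }
        for (nm in names(params)) {
          vel[[nm]] <- config$momentum * vel[[nm]] - lr * acc[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
        step <- step + 1L
        hist[[step]] <- c(step = step, epoch = epoch,
                          loss_cls = lcls, loss_loc = lloc, alpha = alpha_bar)
      }
    }
    stopifnot(identical(frozen_detector$params, detector_before))
    structure(list(network = set_dct_params(dct, params),
                   history = tibble::as_tibble(do.call(rbind, hist)),
                   detector = frozen_detector, config = config),
              class = "dct_fit")
  })
}

# One forward/backward pass of the transform network through the frozen
# detector: DCT head -> (alpha, beta) -> x' = alpha x + beta -> detection
# loss. Gradients with respect to the DCT parameters only; the detector's
# pixel gradient is exact (its cell features are linear in the pixels), the
# parameter chain rules are hand-derived.
dct_grad_step <- function(params, dct, detector, image, boxes) {
  net <- set_dct_params(dct, params)
  fw <- dct_toy_forward(net, image)
  pj <- dct_params_and_jacobian(net, fw$logits)
  x_t <- pj$alpha * image + pj$beta
  res <- detector_loss_grad(detector, x_t, boxes, input_grad = TRUE)
  # backward through the transform into (alpha, beta) ...
  d_alpha <- sum(res$d_image * image)
  d_beta <- sum(res$d_image)
  d_logits <- d_alpha * pj$d_alpha + d_beta * pj$d_beta
  # ... into the head ...
  g_head_w <- outer(fw$pooled, d_logits)
  g_head_b <- d_logits
  d_pooled <- as.vector(params$head_w %*% d_logits)
  # ... and into the pixelwise-linear encoder (mean pooling).
  npix <- nrow(fw$x_mat)
  d_z <- sweep(fw$mask, 2, d_pooled / npix, "*")
  list(loss_cls = res$loss_cls, loss_loc = res$loss_loc,
       alpha = pj$alpha, beta = pj$beta,
       grads = list(enc_w = t(fw$x_mat) %*% d_z,
                    enc_b = colSums(d_z),
                    head_w = g_head_w, head_b = g_head_b))
}

set_dct_params <- function(dct, params) {
  dct$encoder$children[[1]]$params$weight <- params$enc_w
  dct$encoder$children[[1]]$params$bias <- params$enc_b
  dct$head$params$weight <- params$head_w
  dct$head$params$bias <- params$head_b
  dct
}

# --- color sweep -----------------------------------------------------------

#' Detection accuracy over a grid of fixed color transforms
#'
#' Applies every `(alpha, beta)` grid point as a fixed global transform to
#' each image, runs the detector, and scores Average Domain Accuracy. The
#' identity point `(1, 0)` reproduces the plain, no-transform evaluation
#' exactly. This is the static counterpart of the dynamic transform: it
#' shows how much a single well-chosen gain/offset pair could help on a
#' given domain.
#'
#' @param detector A detector (see [detect()]).
#' @param dataset Data frame with list-columns `image`, `boxes` and a
#'   `domain` column.
#' @param alpha_grid,beta_grid Numeric vectors of gains / offsets; either
#'   may be a singleton.
#' @param clip Clamp transformed images to `[0, 1]` (the default mirrors
#'   how a modified image would actually be fed to a detector).
#' @param ... Passed to [detect()].
#' @return A tibble with columns `alpha`, `beta`, `ada`, one row per grid
#'   point, in grid order (`alpha` outer, `beta` inner).
#' @export
color_sweep <- function(detector, dataset, alpha_grid = 1, beta_grid = 0,
                        clip = TRUE, ...) {
  validate_dataset(dataset)
  abort_if(length(alpha_grid) == 0 || length(beta_grid) == 0,
           "grids must be non-empty", class = "dctdetect_validation_error")
  rows <- list()
  for (a in alpha_grid) {
    for (b in beta_grid) {
      tp <- transform_params(a, b)
      report <- evaluate_detector(detector, dataset, transform = tp,
                                  clip = clip, ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(alpha = a, beta = b,
                                                  ada = report$ada)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("color_sweep", class(out))
  out
}

#' Pseudolabel a set of images with a trained detector
#'
#' Treats the detector's thresholded predictions as ground-truth boxes, the
#' minimal form of pseudolabeling used to fold unlabeled test imagery back
#' into training. Boxes carry a provenance flag.
#'
#' @param detector A detector.
#' @param images A list of RGB arrays, or a data frame with an `image`
#'   list-column (extra columns are preserved).
#' @param confidence_threshold Detections at or above this confidence
#'   become pseudolabels.
#' @param ... Passed to [detect()].
#' @return A tibble with `image` and `boxes` list-columns and a `pseudo`
#'   flag; `boxes` rows keep their `confidence`.
#' @export
make_pseudolabels <- function(detector, images, confidence_threshold = 0.5, ...) {
  if (is.data.frame(images)) {
    abort_if(!"image" %in% names(images),
             "`images` data frame needs an `image` list-column",
             class = "dctdetect_validation_error")
    base <- images[setdiff(names(images), "boxes")]
  } else {
    base <- tibble::tibble(image = images)
  }
  base$boxes <- lapply(base$image, function(img) {
    det <- detect(detector, img, ...)
    det[det$confidence >= confidence_threshold, ]
  })
  base$pseudo <- TRUE
  tibble::as_tibble(base)
}

# --- broom-style methods ---------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.detector_fit <- function(x, ...) x$history

#' @export
glance.detector_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(steps = nrow(x$history),
                 epochs = x$config$epochs_detector,
                 final_loss_cls = last$loss_cls,
                 final_loss_loc = last$loss_loc,
                 final_loss = last$loss_cls + last$loss_loc,
                 seed = x$config$seed)
}

#' @export
tidy.dct_fit <- function(x, ...) x$history

#' @export
glance.dct_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(steps = nrow(x$history),
                 epochs = x$config$epochs_dct,
                 final_loss_cls = last$loss_cls,
                 final_loss_loc = last$loss_loc,
                 final_alpha = last$alpha,
                 seed = x$config$seed)
}
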