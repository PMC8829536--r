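#' Minimal dense grid detector
#'
#' A deliberately small single-scale, anchor-free detector that honors the
#' standard dense detection-head contract — per-cell objectness trained with
#' binary cross-entropy, per-cell box regression trained with a GIoU loss,
#' and no regression loss for unassigned cells — while remaining cheap
#' enough to train on a CPU in seconds. It divides the image into
#' `stride x stride` cells, pools each cell into a small intensity feature
#' vector, and runs a one-hidden-layer perceptron per cell emitting an
#' objectness logit and four box offsets.
#'
#' The box decode is: center `= (cell origin + sigmoid(tx, ty)) * stride`,
#' size `= stride * exp(size_range * tanh(tw, th))`, so predicted sizes are
#' bounded multiples of the stride.
#'
#' This is scaffolding around the dynamic color transform, not a production
#' detector; any object with a [detect()] method can replace it.
#'
#' @param stride Grid cell size in pixels.
#' @param hidden Hidden layer width.
#' @param pool Per-cell pooling grid (features per cell = `3 * pool^2`).
#' @param size_range Log-range of the box size decode.
#' @param seed Seed for weight initialization.
#' @return A `toy_detector` model object.
#' @export
toy_detector <- function(stride = 16L, hidden = 24L, pool = 2L,
                         size_range = 1.4, seed = 0L) {
  abort_if(!is_number(stride) || stride < 2,
           "`stride` must be >= 2", class = "dctdetect_validation_error")
  abort_if(stride %% pool != 0,
           "`stride` must be divisible by `pool`",
           class = "dctdetect_validation_error")
  nf <- 3L * pool^2
  params <- withr::with_seed(seed, list(
    w1 = array(stats::rnorm(nf * hidden, sd = 1 / sqrt(nf)), dim = c(nf, hidden)),
    b1 = numeric(hidden),
    w2 = array(stats::rnorm(hidden * 5L, sd = 0.01), dim = c(hidden, 5L)),
    b2 = c(-2, 0, 0, 0, 0)))  # objectness prior starts low
  structure(list(stride = as.integer(stride), hidden = as.integer(hidden),
                 pool = as.integer(pool), size_range = size_range,
                 seed = as.integer(seed), params = params),
            class = c("toy_detector", "dct_detector"))
}

#' @export
print.toy_detector <- function(x, ...) {
  cat(sprintf("<toy_detector> stride %d, %d hidden units, %d parameters\n",
              x$stride, x$hidden,
              sum(vapply(x$params, length, integer(1)))))
  invisible(x)
}

# Per-cell pooled intensity features: each stride x stride cell is divided
# into a pool x pool grid of sub-blocks; the feature vector is the mean
# intensity of every (sub-block, channel) pair. Linear in the pixels, which
# keeps the gradient with respect to the input image exact and cheap.
detector_grid <- function(model, image) {
  d <- dim(image)
  s <- model$stride
  gh <- d[1] %/% s
  gw <- d[2] %/% s
  abort_if(gh < 1 || gw < 1,
           sprintf("image (%d x %d) smaller than one %d px grid cell",
                   d[1], d[2], s),
           class = "dctdetect_shape_error")
  list(gh = gh, gw = gw, n = gh * gw)
}

cell_features <- function(model, image, grid) {
  s <- model$stride
  p <- model$pool
  sub <- s %/% p
  # block-mean the image at sub-block resolution, then gather per cell
  bh <- grid$gh * p
  bw <- grid$gw * p
  cropped <- image[seq_len(bh * sub), seq_len(bw * sub), , drop = FALSE]
  bm <- array(0, dim = c(bh, bw, 3))
  for (c in 1:3) {
    m <- cropped[, , c]
    m <- matrix(colMeans(matrix(m, nrow = sub)), nrow = bh)        # rows pooled
    m <- t(matrix(colMeans(matrix(t(m), nrow = sub)), nrow = bw))  # cols pooled
    bm[, , c] <- m
  }
  feats <- matrix(0, grid$n, 3L * p^2)
  idx <- 0L
  for (c in 1:3) {
    for (dx in seq_len(p)) {
      for (dy in seq_len(p)) {
        idx <- idx + 1L
        sl <- bm[seq.int(dy, by = p, length.out = grid$gh),
                 seq.int(dx, by = p, length.out = grid$gw), c]
        feats[, idx] <- as.vector(sl)  # cell index = row-major within column
      }
    }
  }
  feats
}

# MLP forward over all cells; returns hidden activations and raw outputs.
detector_forward <- function(model, feats) {
  z1 <- sweep(feats %*% model$params$w1, 2, model$params$b1, "+")
  h1 <- tanh(z1)
  out <- sweep(h1 %*% model$params$w2, 2, model$params$b2, "+")
  list(h1 = h1, out = out)
}

# Decode raw per-cell outputs (columns: obj logit, tx, ty, tw, th) into
# image-coordinate boxes. Cells are column-major: cell i sits at grid row
# (i - 1) %% gh + 1, grid column (i - 1) %/% gh + 1.
decode_boxes <- function(model, out, grid) {
  s <- model$stride
  i <- seq_len(grid$n)
  row <- (i - 1L) %% grid$gh
  col <- (i - 1L) %/% grid$gh
  cx <- (col + stats::plogis(out[, 2])) * s
  cy <- (row + stats::plogis(out[, 3])) * s
  w <- s * exp(model$size_range * tanh(out[, 4]))
  h <- s * exp(model$size_range * tanh(out[, 5]))
  tibble::tibble(x_min = cx - w / 2, y_min = cy - h / 2,
                 x_max = cx + w / 2, y_max = cy + h / 2)
}

# A cell is positive when a ground-truth box center falls inside it; if
# several centers share a cell the smallest-area box wins. Returns the
# positive cell indices and their target boxes, aligned.
assign_targets <- function(model, boxes, grid) {
  validate_boxes(boxes)
  if (nrow(boxes) == 0) {
    return(list(cells = integer(), boxes = empty_boxes()))
  }
  s <- model$stride
  cx <- (boxes$x_min + boxes$x_max) / 2
  cy <- (boxes$y_min + boxes$y_max) / 2
  col <- floor(cx / s)
  row <- floor(cy / s)
  inside <- col >= 0 & col < grid$gw & row >= 0 & row < grid$gh
  if (!any(inside)) return(list(cells = integer(), boxes = empty_boxes()))
  cell <- col[inside] * grid$gh + row[inside] + 1L
  area <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
  ord <- order(cell, area[inside])
  keep <- ord[!duplicated(cell[ord])]
  kept_rows <- which(inside)[keep]
  list(cells = as.integer(cell[keep]),
       boxes = boxes[kept_rows, box_cols])
}

#' Detection loss of dense grid predictions
#'
#' The training objective is the sum of a classification and a localization
#' term: binary cross-entropy over the per-cell objectness scores, plus the
#' mean of `1 - GIoU` over positive (object-assigned) cells. Cells with no
#' assigned ground truth contribute no localization loss.
#'
#' @param predictions List with `objectness` (per-cell probabilities in
#'   `[0, 1]`) and `boxes` (data frame of decoded boxes, one row per cell).
#' @param targets List with `positive` (logical per-cell mask) and `boxes`
#'   (data frame with one row per positive cell, in cell order).
#' @return Named numeric vector `c(loss_cls, loss_loc)`.
#' @export
detection_loss <- function(predictions, targets) {
  p <- predictions$objectness
  abort_if(is.null(p) || length(p) == 0,
           "`predictions$objectness` must be a non-empty probability vector",
           class = "dctdetect_validation_error")
  abort_if(any(p < 0 | p > 1), "objectness must be in [0, 1]",
           class = "dctdetect_validation_error")
  y <- as.numeric(targets$positive)
  abort_if(length(y) != length(p),
           "predictions and targets cover different grids",
           class = "dctdetect_validation_error")
  eps <- 1e-12
  loss_cls <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  pos <- which(targets$positive)
  loss_loc <- if (length(pos) == 0) 0 else {
    validate_boxes(targets$boxes)
    mean(1 - giou_rows(predictions$boxes[pos, , drop = FALSE], targets$boxes))
  }
  c(loss_cls = loss_cls, loss_loc = loss_loc)
}

#' Run a detector on an image
#'
#' `detect()` is the pluggable detector contract: anything implementing it
#' (or any plain function `f(image)` returning a detection data frame) can
#' be used by the training pipeline, the ensemble and the evaluation
#' metric. Detections are tibbles with box coordinates, a confidence in
#' `[0, 1]` and an integer `class_label` (always 0 for the single-class
#' setting), sorted by descending confidence.
#'
#' @param detector A detector model.
#' @param image RGB image array.
#' @param ... Method-specific options.
#' @return A tibble of detections.
#' @export
detect <- function(detector, image, ...) {
  if (is.function(detector)) return(detector(image, ...))
  UseMethod("detect")
}

#' @rdname detect
#' @param confidence_threshold Keep cells with objectness strictly above
#'   this value.
#' @param nms_iou Greedy non-maximum suppression IoU threshold.
#' @export
detect.toy_detector <- function(detector, image, confidence_threshold = 0.5,
                                nms_iou = 0.5, ...) {
  toy_detect(detector, image, confidence_threshold, nms_iou)
}

#' @rdname detect
#' @export
toy_detect <- function(detector, image, confidence_threshold = 0.5,
                       nms_iou = 0.5) {
  validate_image(image)
  grid <- detector_grid(detector, image)
  fwd <- detector_forward(detector, cell_features(detector, image, grid))
  conf <- stats::plogis(fwd$out[, 1])
  keep <- which(conf > confidence_threshold)
  if (length(keep) == 0) return(empty_detections())
  boxes <- decode_boxes(detector, fwd$out, grid)[keep, ]
  det <- tibble::tibble(boxes, confidence = conf[keep], class_label = 0L)
  det <- det[order(-det$confidence), ]
  det[nms_keep(det, nms_iou), ]
}

# --- gradients -------------------------------------------------------------

# Loss and hand-derived gradient for one image. The objectness part is
# analytic; the GIoU part uses central finite differences on the four box
# offsets of each positive cell (the decode is smooth and bounded, so a
# fixed step is safe). Returns the loss pieces, parameter gradients, and
# optionally the gradient with respect to the input pixels (needed when a
# color transform upstream is being trained through a frozen detector).
detector_loss_grad <- function(model, image, boxes, input_grad = FALSE) {
  grid <- detector_grid(model, image)
  feats <- cell_features(model, image, grid)
  fwd <- detector_forward(model, feats)
  out <- fwd$out
  n <- grid$n
  tgt <- assign_targets(model, boxes, grid)
  y <- numeric(n)
  y[tgt$cells] <- 1

  p_obj <- stats::plogis(out[, 1])
  eps <- 1e-12
  loss_cls <- -mean(y * log(p_obj + eps) + (1 - y) * log(1 - p_obj + eps))

  d_out <- matrix(0, n, 5L)
  d_out[, 1] <- (p_obj - y) / n

  npos <- length(tgt$cells)
  loss_loc <- 0
  if (npos > 0) {
    s <- model$stride
    tb <- as.matrix(tgt$boxes[box_cols])
    # scalar decode of one cell, cheap enough for finite differences
    decode1 <- function(o, cell) {
      row <- (cell - 1L) %% grid$gh
      col <- (cell - 1L) %/% grid$gh
      cx <- (col + stats::plogis(o[1])) * s
      cy <- (row + stats::plogis(o[2])) * s
      w <- s * exp(model$size_range * tanh(o[3]))
      hh <- s * exp(model$size_range * tanh(o[4]))
      c(cx - w / 2, cy - hh / 2, cx + w / 2, cy + hh / 2)
    }
    h <- 1e-4
    for (k in seq_len(npos)) {
      cell <- tgt$cells[k]
      o <- out[cell, 2:5]
      loss_loc <- loss_loc +
        (1 - iou_giou(decode1(o, cell), tb[k, ])$giou) / npos
      for (j in 1:4) {
        op <- o; op[j] <- op[j] + h
        om <- o; om[j] <- om[j] - h
        gp <- iou_giou(decode1(op, cell), tb[k, ])$giou
        gm <- iou_giou(decode1(om, cell), tb[k, ])$giou
        d_out[cell, j + 1L] <- d_out[cell, j + 1L] - (gp - gm) / (2 * h) / npos
      }
    }
  }

  d_h1 <- d_out %*% t(model$params$w2)
  d_z1 <- d_h1 * (1 - fwd$h1^2)
  grads <- list(w1 = t(feats) %*% d_z1,
                b1 = colSums(d_z1),
                w2 = t(fwd$h1) %*% d_out,
                b2 = colSums(d_out))

  d_image <- NULL
  if (input_grad) {
    d_feats <- d_z1 %*% t(model$params$w1)
    d_image <- features_input_grad(model, d_feats, grid, dim(image))
  }

  list(loss_cls = loss_cls, loss_loc = loss_loc, grads = grads,
       d_image = d_image, n_pos = npos)
}

# Spread per-feature gradients back to pixels: every feature is the mean of
# a sub x sub pixel block in one channel.
features_input_grad <- function(model, d_feats, grid, img_dim) {
  s <- model$stride
  p <- model$pool
  sub <- s %/% p
  d_img <- array(0, dim = img_dim)
  idx <- 0L
  for (c in 1:3) {
    for (dx in seq_len(p)) {
      for (dy in seq_len(p)) {
        idx <- idx + 1L
        g <- matrix(d_feats[, idx], grid$gh, grid$gw) / sub^2
        # expand each grid entry over its sub x sub block
        rows_base <- (seq_len(grid$gh) - 1L) * s + (dy - 1L) * sub
        cols_base <- (seq_len(grid$gw) - 1L) * s + (dx - 1L) * sub
        for (r in seq_len(sub)) {
          for (cc in seq_len(sub)) {
            d_img[rows_base + r, cols_base + cc, c] <-
              d_img[rows_base + r, cols_base + cc, c] + g
          }
        }
      }
    }
  }
  d_img
}
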