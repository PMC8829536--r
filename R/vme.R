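#' Voting-based model ensemble configuration
#'
#' @param tau IoU threshold above which two boxes count as "similar"
#'   (strictly greater). Default 0.6.
#' @return A `vme_config` object.
#' @export
vme_config <- function(tau = 0.6) {
  abort_if(!is_number(tau) || tau <= 0 || tau >= 1,
           "`tau` must be in (0, 1)", class = "dctdetect_validation_error")
  structure(list(tau = tau), class = "vme_config")
}

#' Build a prediction set
#'
#' A prediction set is one model's (or one augmented view's) detections on
#' an image, tagged with its source id.
#'
#' @param source Integer id, distinct across an ensemble.
#' @param detections A detection data frame (boxes, `confidence`,
#'   optionally `class_label`).
#' @return A `prediction_set` tibble with a `source` column.
#' @export
prediction_set <- function(source, detections) {
  if (nrow(detections) > 0) validate_boxes(detections, "detections")
  abort_if(nrow(detections) > 0 &&
             (!"confidence" %in% names(detections) ||
                any(detections$confidence < 0 | detections$confidence > 1)),
           "detections need a `confidence` column in [0, 1]",
           class = "dctdetect_validation_error")
  out <- tibble::as_tibble(detections)
  if (nrow(out) == 0) out <- empty_detections()
  out$source <- as.integer(source)
  out
}

pool_sets <- function(sets) {
  abort_if(length(sets) == 0, "the ensemble has no prediction sets",
           class = "dctdetect_validation_error")
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (!"source" %in% names(s)) s <- prediction_set(i, s)
    s
  })
  ids <- vapply(sets, function(s) s$source[1] %||% NA_integer_, integer(1))
  ids <- ids[!is.na(ids)]
  abort_if(anyDuplicated(ids) > 0, "prediction set source ids must be distinct",
           class = "dctdetect_validation_error")
  dplyr::bind_rows(sets)
}

#' Fuse prediction sets by majority voting
#'
#' Given `K` prediction sets for the same image, boxes are clustered by
#' cross-set similarity (IoU strictly above `tau`), a cluster is kept only
#' when it has strictly more than `floor(K / 2)` members — i.e. a strict
#' majority of models agree on the box, counting the seed itself — and each
#' kept cluster is collapsed to a single detection by averaging member
#' coordinates and confidences.
#'
#' Clustering is greedy: boxes are visited in descending confidence; the
#' best unassigned box seeds a cluster, which absorbs at most one unassigned
#' box per source (the most confident one among those with IoU above `tau`
#' with the seed).
#'
#' With `K = 1` every box forms a kept singleton cluster, so a single
#' model's predictions pass through unchanged.
#'
#' @param sets A list of prediction sets (detection data frames; a `source`
#'   column is added positionally when absent).
#' @param config A [vme_config()].
#' @return A tibble of fused detections sorted by descending confidence.
#' @export
vme_fuse <- function(sets, config = vme_config()) {
  pooled <- pool_sets(sets)
  k <- length(sets)
  need <- floor(k / 2)
  if (nrow(pooled) == 0) return(empty_detections())
  ord <- order(-pooled$confidence)
  pooled <- pooled[ord, ]
  n <- nrow(pooled)
  assigned <- logical(n)
  m <- box_iou_matrix(pooled, pooled)
  fused <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    cand <- which(!assigned & m[i, ] > config$tau)
    # at most one member per source; candidates are in confidence order
    members <- cand[!duplicated(pooled$source[cand])]
    assigned[members] <- TRUE
    if (length(members) > need) {
      fused[[length(fused) + 1L]] <- tibble::tibble(
        x_min = mean(pooled$x_min[members]),
        y_min = mean(pooled$y_min[members]),
        x_max = mean(pooled$x_max[members]),
        y_max = mean(pooled$y_max[members]),
        confidence = mean(pooled$confidence[members]),
        class_label = 0L)
    }
  }
  if (length(fused) == 0) return(empty_detections())
  out <- dplyr::bind_rows(fused)
  out[order(-out$confidence), ]
}

#' Reference implementation of voting fusion
#'
#' An exhaustive, loop-based restatement of the [vme_fuse()] keep/average
#' rule for small instances, used to validate the production path. Refuses
#' instances with more than 50 boxes.
#'
#' @inheritParams vme_fuse
#' @return A tibble of fused detections.
#' @export
vme_fuse_oracle <- function(sets, config = vme_config()) {
  pooled <- pool_sets(sets)
  abort_if(nrow(pooled) > 50,
           "oracle fusion only accepts instances with <= 50 boxes",
           class = "dctdetect_validation_error")
  k <- length(sets)
  if (nrow(pooled) == 0) return(empty_detections())
  boxes <- pooled[order(-pooled$confidence), ]
  taken <- rep(FALSE, nrow(boxes))
  out <- empty_detections()
  repeat {
    seed <- NA_integer_
    for (i in seq_len(nrow(boxes))) {
      if (!taken[i]) { seed <- i; break }
    }
    if (is.na(seed)) break
    members <- integer()
    seen_sources <- integer()
    for (j in seq_len(nrow(boxes))) {
      if (taken[j]) next
      ov <- iou(c(boxes$x_min[seed], boxes$y_min[seed],
                  boxes$x_max[seed], boxes$y_max[seed]),
                c(boxes$x_min[j], boxes$y_min[j],
                  boxes$x_max[j], boxes$y_max[j]))
      if (ov > config$tau && !(boxes$source[j] %in% seen_sources)) {
        members <- c(members, j)
        seen_sources <- c(seen_sources, boxes$source[j])
      }
    }
    taken[members] <- TRUE
    if (length(members) > floor(k / 2)) {
      out <- rbind(out, tibble::tibble(
        x_min = mean(boxes$x_min[members]),
        y_min = mean(boxes$y_min[members]),
        x_max = mean(boxes$x_max[members]),
        y_max = mean(boxes$y_max[members]),
        confidence = mean(boxes$confidence[members]),
        class_label = 0L))
    }
  }
  out[order(-out$confidence), ]
}

# --- test-time augmentation ------------------------------------------------

tta_tags <- c("identity", "flip_lr", "flip_ud", "rot90", "rot180", "rot270")

apply_tta_image <- function(image, tag) {
  h <- dim(image)[1]; w <- dim(image)[2]
  switch(tag,
    identity = image,
    flip_lr = flip_image(image, TRUE),
    flip_ud = flip_image(image, FALSE),
    rot90 = aperm(image[rev(seq_len(h)), , , drop = FALSE], c(2, 1, 3)),
    rot180 = flip_image(flip_image(image, TRUE), FALSE),
    rot270 = aperm(image[, rev(seq_len(w)), , drop = FALSE], c(2, 1, 3)))
}

# Map boxes detected in the augmented frame back to original coordinates.
# h, w are the ORIGINAL image dimensions.
invert_tta_boxes <- function(boxes, tag, h, w) {
  if (nrow(boxes) == 0) return(boxes)
  out <- boxes
  switch(tag,
    identity = out,
    flip_lr = { out$x_min <- w - boxes$x_max; out$x_max <- w - boxes$x_min; out },
    flip_ud = { out$y_min <- h - boxes$y_max; out$y_max <- h - boxes$y_min; out },
    rot90 = {  # clockwise rotation: (x, y) -> (h - y, x)
      out$x_min <- boxes$y_min; out$x_max <- boxes$y_max
      out$y_min <- h - boxes$x_max; out$y_max <- h - boxes$x_min
      out
    },
    rot180 = {
      out$x_min <- w - boxes$x_max; out$x_max <- w - boxes$x_min
      out$y_min <- h - boxes$y_max; out$y_max <- h - boxes$y_min
      out
    },
    rot270 = {  # counterclockwise rotation: (x, y) -> (y, w - x)
      out$x_min <- w - boxes$y_max; out$x_max <- w - boxes$y_min
      out$y_min <- boxes$x_min; out$y_max <- boxes$x_max
      out
    })
}

#' Test-time augmentation predictions
#'
#' Runs the detector on transformed copies of an image (flips and
#' 90-degree rotations) and maps every detection back to original-image
#' coordinates, producing one prediction set per augmentation — the input
#' the voting ensemble [vme_fuse()] expects.
#'
#' @param detector A detector (see [detect()]).
#' @param image RGB image array.
#' @param augmentations Character vector from `"identity"`, `"flip_lr"`,
#'   `"flip_ud"`, `"rot90"`, `"rot180"`, `"rot270"`.
#' @param ... Passed to [detect()].
#' @return A list of prediction sets, one per augmentation (`K` sets).
#' @export
tta_predict <- function(detector, image,
                        augmentations = c("identity", "flip_lr", "flip_ud"),
                        ...) {
  validate_image(image)
  bad <- setdiff(augmentations, tta_tags)
  abort_if(length(bad) > 0,
           paste0("unknown augmentation tag(s): ", paste(bad, collapse = ", ")),
           class = "dctdetect_config_error")
  h <- dim(image)[1]; w <- dim(image)[2]
  lapply(seq_along(augmentations), function(i) {
    tag <- augmentations[i]
    det <- detect(detector, apply_tta_image(image, tag), ...)
    prediction_set(i, invert_tta_boxes(det, tag, h, w))
  })
}
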