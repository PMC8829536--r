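# Axis-aligned box geometry. Boxes are continuous, 0-based pixel
# coordinates (origin top-left, y downward); area = (x_max - x_min) *
# (y_max - y_min).

as_box <- function(b, arg = "box") {
  if (is.data.frame(b)) {
    validate_boxes(b, arg)
    abort_if(nrow(b) != 1L, paste0("`", arg, "` must be a single box"),
             class = "dctdetect_validation_error")
    b <- c(b$x_min, b$y_min, b$x_max, b$y_max)
  }
  abort_if(!is.numeric(b) || length(b) != 4L || !all(is.finite(b)),
           paste0("`", arg, "` must be 4 finite numbers (x_min, y_min, x_max, y_max)"),
           class = "dctdetect_validation_error")
  abort_if(b[1] >= b[3] || b[2] >= b[4],
           paste0("`", arg, "` is degenerate (need x_min < x_max, y_min < y_max)"),
           class = "dctdetect_validation_error")
  as.numeric(b)
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes: numeric vectors `c(x_min, y_min, x_max, y_max)` or
#'   one-row data frames with those columns.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes, 1 for identical boxes.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  a <- as_box(a, "a"); b <- as_box(b, "b")
  iou_giou(a, b)$iou
}

#' Generalized intersection over union of two boxes
#'
#' GIoU subtracts from IoU the fraction of the smallest enclosing box not
#' covered by the union:
#' \deqn{GIoU = IoU - \frac{|C| - |A \cup B|}{|C|}}
#' It equals IoU for overlapping boxes whose union fills the enclosing hull,
#' ranges over `(-1, 1]`, and `1 - GIoU` is the localization loss used for
#' detector training.
#'
#' @inheritParams iou
#' @return GIoU in `(-1, 1]`.
#' @examples
#' giou(c(0, 0, 1, 1), c(9, 9, 10, 10))  # -0.98
#' @export
giou <- function(a, b) {
  a <- as_box(a, "a"); b <- as_box(b, "b")
  iou_giou(a, b)$giou
}

iou_giou <- function(a, b) {
  a <- unname(a); b <- unname(b)
  inter_w <- pmax(0, pmin(a[3], b[3]) - pmax(a[1], b[1]))
  inter_h <- pmax(0, pmin(a[4], b[4]) - pmax(a[2], b[2]))
  inter <- inter_w * inter_h
  area_a <- (a[3] - a[1]) * (a[4] - a[2])
  area_b <- (b[3] - b[1]) * (b[4] - b[2])
  union <- area_a + area_b - inter
  enclose <- (pmax(a[3], b[3]) - pmin(a[1], b[1])) *
    (pmax(a[4], b[4]) - pmin(a[2], b[2]))
  iou <- inter / union
  list(iou = iou, giou = iou - (enclose - union) / enclose)
}

# Vectorized IoU between all rows of boxes `a` and all rows of `b`;
# returns an nrow(a) x nrow(b) matrix. Inputs are matrices or data frames
# with the standard four columns.
box_iou_matrix <- function(a, b) {
  if (is.data.frame(a)) a <- as.matrix(a[box_cols])
  if (is.data.frame(b)) b <- as.matrix(b[box_cols])
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(0, na, nb))
  ix_min <- pmax(matrix(a[, 1], na, nb), matrix(b[, 1], na, nb, byrow = TRUE))
  iy_min <- pmax(matrix(a[, 2], na, nb), matrix(b[, 2], na, nb, byrow = TRUE))
  ix_max <- pmin(matrix(a[, 3], na, nb), matrix(b[, 3], na, nb, byrow = TRUE))
  iy_max <- pmin(matrix(a[, 4], na, nb), matrix(b[, 4], na, nb, byrow = TRUE))
  inter <- pmax(0, ix_max - ix_min) * pmax(0, iy_max - iy_min)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (matrix(area_a, na, nb) + matrix(area_b, na, nb, byrow = TRUE) - inter)
}

# Row-aligned GIoU between two equally sized box matrices.
giou_rows <- function(a, b) {
  if (is.data.frame(a)) a <- as.matrix(a[box_cols])
  if (is.data.frame(b)) b <- as.matrix(b[box_cols])
  inter <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1])) *
    pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  union <- area_a + area_b - inter
  enclose <- (pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])) *
    (pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2]))
  inter / union - (enclose - union) / enclose
}

# Greedy non-maximum suppression; detections must be sorted by descending
# confidence. Returns the row indices kept.
nms_keep <- function(boxes, threshold) {
  n <- nrow(boxes)
  if (n == 0) return(integer())
  keep <- logical(n)
  alive <- rep(TRUE, n)
  m <- box_iou_matrix(boxes, boxes)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[m[i, ] > threshold] <- FALSE
  }
  which(keep)
}
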