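# Internal validation helpers shared across modules.

abort_if <- function(cond, msg, class = "dctdetect_error") {
  if (isTRUE(cond)) {
    rlang::abort(msg, class = c(class, "dctdetect_error"))
  }
  invisible(NULL)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Validate an RGB image array
#'
#' Images are plain numeric arrays of shape height x width x 3, with
#' intensities in normalized units (nominal range `[0, 1]`). This helper
#' checks shape and finiteness and returns the array invisibly so it can be
#' used at function entry points.
#'
#' @param image A numeric array.
#' @param arg Name used in error messages.
#' @return The validated array, invisibly.
#' @keywords internal
validate_image <- function(image, arg = "image") {
  abort_if(!is.array(image) || !is.numeric(image),
           paste0("`", arg, "` must be a numeric array"),
           class = "dctdetect_shape_error")
  d <- dim(image)
  abort_if(length(d) != 3L || d[3] != 3L,
           paste0("`", arg, "` must have shape height x width x 3 (got ",
                  paste(d, collapse = " x "), ")"),
           class = "dctdetect_shape_error")
  abort_if(d[1] < 1L || d[2] < 1L,
           paste0("`", arg, "` must have height >= 1 and width >= 1"),
           class = "dctdetect_shape_error")
  abort_if(!all(is.finite(image)),
           paste0("`", arg, "` contains non-finite values"),
           class = "dctdetect_validation_error")
  invisible(image)
}

# Boxes travel as tibbles with columns x_min, y_min, x_max, y_max
# (continuous pixel coordinates, origin top-left, y pointing down).
box_cols <- c("x_min", "y_min", "x_max", "y_max")

validate_boxes <- function(boxes, arg = "boxes") {
  abort_if(!is.data.frame(boxes),
           paste0("`", arg, "` must be a data frame of boxes"),
           class = "dctdetect_validation_error")
  missing <- setdiff(box_cols, names(boxes))
  abort_if(length(missing) > 0,
           paste0("`", arg, "` is missing columns: ",
                  paste(missing, collapse = ", ")),
           class = "dctdetect_validation_error")
  if (nrow(boxes) > 0) {
    m <- as.matrix(boxes[box_cols])
    abort_if(!all(is.finite(m)),
             paste0("`", arg, "` contains non-finite coordinates"),
             class = "dctdetect_validation_error")
    abort_if(any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max),
             paste0("`", arg, "` contains degenerate boxes (need x_min < x_max and y_min < y_max)"),
             class = "dctdetect_validation_error")
  }
  invisible(boxes)
}

empty_boxes <- function() {
  tibble::tibble(x_min = double(), y_min = double(),
                 x_max = double(), y_max = double())
}

empty_detections <- function() {
  tibble::tibble(x_min = double(), y_min = double(),
                 x_max = double(), y_max = double(),
                 confidence = double(), class_label = integer())
}
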