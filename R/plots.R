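#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot a color-sweep table
#'
#' ADA as a function of the gain `alpha`, one line per offset `beta`; the
#' identity point `(1, 0)` is highlighted as the no-transform baseline.
#'
#' @param object A `color_sweep` tibble from [color_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.color_sweep <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$alpha, y = .data$ada,
                                    colour = factor(.data$beta),
                                    group = factor(.data$beta))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(alpha), y = "ADA", colour = expression(beta)) +
    ggplot2::theme_minimal()
  idpt <- object[object$alpha == 1 & object$beta == 0, ]
  if (nrow(idpt) > 0) {
    p <- p + ggplot2::geom_point(data = idpt, colour = "orange", size = 3)
  }
  p
}

#' Plot an evaluation report
#'
#' Per-domain accuracies with the cross-domain ADA as a reference line.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$per_domain,
                  ggplot2::aes(x = .data$domain, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$ada, linetype = "dashed") +
    ggplot2::annotate("text", x = Inf, y = object$ada,
                      label = sprintf("ADA = %.3f", object$ada),
                      hjust = 1.1, vjust = -0.5) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "domain", y = "domain accuracy") +
    ggplot2::theme_minimal()
}

plot_loss_history <- function(history) {
  long <- tidyr::pivot_longer(history[c("step", "loss_cls", "loss_loc")],
                              cols = c("loss_cls", "loss_loc"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gradient step", y = "loss") +
    ggplot2::theme_minimal()
}

#' Plot training loss curves
#'
#' @param object A `detector_fit` or `dct_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.detector_fit <- function(object, ...) plot_loss_history(object$history)

#' @rdname autoplot.detector_fit
#' @export
autoplot.dct_fit <- function(object, ...) plot_loss_history(object$history)

#' Plot an annotated scene
#'
#' Renders the image with its ground-truth boxes (and optionally a second
#' set of detections) — handy for eyeballing synthetic scenes and detector
#' output.
#'
#' @param image RGB image array.
#' @param boxes Ground-truth boxes (drawn green), optional.
#' @param detections Predicted boxes (drawn red), optional.
#' @return A ggplot object.
#' @export
plot_scene <- function(image, boxes = NULL, detections = NULL) {
  validate_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  df <- expand.grid(y = seq_len(h) - 0.5, x = seq_len(w) - 0.5)
  df$fill <- grDevices::rgb(as.vector(image[, , 1]), as.vector(image[, , 2]),
                            as.vector(image[, , 3]))
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_raster(ggplot2::aes(x = .data$x, y = .data$y),
                         fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  add_rects <- function(p, b, colour) {
    if (is.null(b) || nrow(b) == 0) return(p)
    p + ggplot2::geom_rect(data = b,
                           ggplot2::aes(xmin = .data$x_min, xmax = .data$x_max,
                                        ymin = .data$y_min, ymax = .data$y_max),
                           fill = NA, colour = colour, linewidth = 0.4)
  }
  p <- add_rects(p, boxes, "green")
  add_rects(p, detections, "red")
}
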