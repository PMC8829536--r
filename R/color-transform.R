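#' Color transform parameters
#'
#' A dynamic color transform (DCT) modulates an RGB image by a single global
#' linear map applied identically to all three channels:
#' \deqn{x' = \alpha \cdot x + \beta}
#' where `alpha` is a unitless multiplicative gain and `beta` an additive
#' offset in normalized intensity units. Channel parameters are deliberately
#' unified: one `(alpha, beta)` pair serves R, G and B alike, which keeps the
#' transform a two-parameter illumination correction rather than a full color
#' remap.
#'
#' @param alpha Gain, must be positive and finite.
#' @param beta Offset, must be finite.
#' @return An object of class `transform_params`.
#' @examples
#' p <- transform_params(1.2, -0.05)
#' p$alpha
#' @export
transform_params <- function(alpha, beta) {
  abort_if(!is_number(alpha) || alpha <= 0,
           "`alpha` must be a single finite positive number",
           class = "dctdetect_validation_error")
  abort_if(!is_number(beta), "`beta` must be a single finite number",
           class = "dctdetect_validation_error")
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf("<transform_params> alpha = %.6g, beta = %.6g\n", x$alpha, x$beta))
  invisible(x)
}

#' Apply a global linear color transform to an image
#'
#' Every pixel intensity `v` becomes `alpha * v + beta`, identically on all
#' three channels. With `clip = TRUE` the result is clamped to `[0, 1]`
#' (appropriate for export and visualization); with `clip = FALSE` the map
#' stays exactly linear, which is what training through the transform needs.
#'
#' @param image Numeric array height x width x 3, normalized intensities.
#' @param params A [transform_params()] object.
#' @param clip Clamp output to `[0, 1]`? Default `FALSE`.
#' @return A transformed array of the same shape.
#' @examples
#' img <- array(0.5, dim = c(4, 4, 3))
#' out <- apply_color_transform(img, transform_params(0.7, 0))
#' out[1, 1, 1]  # 0.35
#' @export
apply_color_transform <- function(image, params, clip = FALSE) {
  validate_image(image)
  abort_if(!inherits(params, "transform_params"),
           "`params` must be created by transform_params()",
           class = "dctdetect_validation_error")
  out <- params$alpha * image + params$beta
  if (isTRUE(clip)) {
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

#' Configuration of the regression parameter head
#'
#' The regression formulation squashes two unbounded network outputs into
#' bounded transform parameters:
#' \deqn{\alpha = \alpha_{max} \, \mathrm{sigmoid}(\alpha_x), \qquad
#'       \beta = \beta_{max} \, \frac{2}{\pi} \arctan(\beta_x)}
#' so that `alpha` ranges over `(0, alpha_max)` and `beta` over
#' `(-beta_max, beta_max)`. Defaults are `alpha_max = 2`, `beta_max = 0.1`,
#' giving ranges `(0, 2)` and `(-0.1, 0.1)`.
#'
#' @param alpha_max Upper bound on the gain; positive.
#' @param beta_max Bound on the absolute offset; positive.
#' @return A `regression_head_config` object.
#' @export
regression_head_config <- function(alpha_max = 2, beta_max = 0.1) {
  abort_if(!is_number(alpha_max) || alpha_max <= 0,
           "`alpha_max` must be positive", class = "dctdetect_validation_error")
  abort_if(!is_number(beta_max) || beta_max <= 0,
           "`beta_max` must be positive", class = "dctdetect_validation_error")
  structure(list(alpha_max = alpha_max, beta_max = beta_max),
            class = "regression_head_config")
}

#' Configuration of the classification parameter head
#'
#' The classification formulation restricts the transform parameters to
#' discrete value grids
#' \deqn{V_\alpha = \{ i_\alpha k : k = 1, \dots, k_{max} \}, \qquad
#'       V_\beta  = \{ i_\beta j : j = -j_{max}, \dots, j_{max} \}}
#' and predicts a probability distribution over each grid; the emitted
#' parameter is the expectation under that distribution. Defaults
#' (`i_alpha = 0.1`, `k_max = 20`, `i_beta = 0.1`, `j_max = 2`) give value
#' ranges `[0.1, 2]` for `alpha` and `[-0.2, 0.2]` for `beta`.
#'
#' @param i_alpha Step size of the alpha grid; positive.
#' @param k_max Number of alpha levels; at least 1.
#' @param i_beta Step size of the beta grid; positive.
#' @param j_max Half-range of the beta grid; non-negative. The beta grid has
#'   `2 * j_max + 1` levels and always contains 0.
#' @return A `classification_head_config` object.
#' @export
classification_head_config <- function(i_alpha = 0.1, k_max = 20,
                                       i_beta = 0.1, j_max = 2) {
  abort_if(!is_number(i_alpha) || i_alpha <= 0,
           "`i_alpha` must be positive", class = "dctdetect_validation_error")
  abort_if(!is_number(i_beta) || i_beta <= 0,
           "`i_beta` must be positive", class = "dctdetect_validation_error")
  abort_if(!is_number(k_max) || k_max < 1 || k_max != round(k_max),
           "`k_max` must be an integer >= 1", class = "dctdetect_validation_error")
  abort_if(!is_number(j_max) || j_max < 0 || j_max != round(j_max),
           "`j_max` must be an integer >= 0", class = "dctdetect_validation_error")
  structure(list(i_alpha = i_alpha, k_max = as.integer(k_max),
                 i_beta = i_beta, j_max = as.integer(j_max)),
            class = "classification_head_config")
}

#' Discrete alpha value grid
#'
#' @param i_alpha Step size; positive.
#' @param k_max Number of levels; at least 1.
#' @return Numeric vector `i_alpha * (1:k_max)`, strictly increasing.
#' @examples
#' build_alpha_values(0.1, 10)  # 0.1, 0.2, ..., 1.0
#' @export
build_alpha_values <- function(i_alpha, k_max) {
  abort_if(!is_number(i_alpha) || i_alpha <= 0,
           "`i_alpha` must be positive", class = "dctdetect_validation_error")
  abort_if(!is_number(k_max) || k_max < 1 || k_max != round(k_max),
           "`k_max` must be an integer >= 1", class = "dctdetect_validation_error")
  i_alpha * seq_len(k_max)
}

#' Discrete beta value grid
#'
#' @param i_beta Step size; positive.
#' @param j_max Half-range; non-negative integer.
#' @return Numeric vector `i_beta * (-j_max:j_max)`: symmetric about zero,
#'   of length `2 * j_max + 1`, always containing 0.
#' @examples
#' build_beta_values(0.1, 2)  # -0.2, -0.1, 0, 0.1, 0.2
#' @export
build_beta_values <- function(i_beta, j_max) {
  abort_if(!is_number(i_beta) || i_beta <= 0,
           "`i_beta` must be positive", class = "dctdetect_validation_error")
  abort_if(!is_number(j_max) || j_max < 0 || j_max != round(j_max),
           "`j_max` must be a non-negative integer",
           class = "dctdetect_validation_error")
  i_beta * seq.int(-j_max, j_max)
}

#' Raw head outputs of a DCT network
#'
#' `regression_head_output()` wraps the two unbounded pre-activations of the
#' regression head; `classification_head_output()` wraps the two probability
#' vectors of the classification head (each must be non-negative and sum to 1
#' within 1e-6).
#'
#' @param alpha_preact,beta_preact Unbounded real pre-activations.
#' @return A `head_output` object tagged with its formulation.
#' @export
regression_head_output <- function(alpha_preact, beta_preact) {
  abort_if(!is.numeric(alpha_preact) || length(alpha_preact) != 1L ||
             is.na(alpha_preact),
           "`alpha_preact` must be a single real number",
           class = "dctdetect_validation_error")
  abort_if(!is.numeric(beta_preact) || length(beta_preact) != 1L ||
             is.na(beta_preact),
           "`beta_preact` must be a single real number",
           class = "dctdetect_validation_error")
  structure(list(formulation = "regression",
                 alpha_preact = as.numeric(alpha_preact),
                 beta_preact = as.numeric(beta_preact)),
            class = "head_output")
}

#' @rdname regression_head_output
#' @param prob_alpha Probability vector over the alpha grid (length `k_max`).
#' @param prob_beta Probability vector over the beta grid
#'   (length `2 * j_max + 1`).
#' @export
classification_head_output <- function(prob_alpha, prob_beta) {
  check_prob <- function(p, arg) {
    abort_if(!is.numeric(p) || length(p) < 1L || anyNA(p),
             paste0("`", arg, "` must be a numeric probability vector"),
             class = "dctdetect_validation_error")
    abort_if(any(p < 0),
             paste0("`", arg, "` has negative entries"),
             class = "dctdetect_validation_error")
    abort_if(abs(sum(p) - 1) > 1e-6,
             paste0("`", arg, "` must sum to 1 (within 1e-6)"),
             class = "dctdetect_validation_error")
  }
  check_prob(prob_alpha, "prob_alpha")
  check_prob(prob_beta, "prob_beta")
  structure(list(formulation = "classification",
                 prob_alpha = as.numeric(prob_alpha),
                 prob_beta = as.numeric(prob_beta)),
            class = "head_output")
}

#' Map regression head outputs to transform parameters
#'
#' Applies the bounded squashing of the regression formulation (see
#' [regression_head_config()]). The gain is strictly inside
#' `(0, alpha_max)` and the offset strictly inside `(-beta_max, beta_max)`
#' for every finite pre-activation.
#'
#' @param head A regression-tagged [regression_head_output()].
#' @param config A [regression_head_config()].
#' @return A [transform_params()] object.
#' @examples
#' regression_transform_params(regression_head_output(0, 0),
#'                             regression_head_config())  # alpha 1, beta 0
#' @export
regression_transform_params <- function(head, config = regression_head_config()) {
  abort_if(!inherits(head, "head_output") || head$formulation != "regression",
           "`head` must be a regression-tagged head output",
           class = "dctdetect_formulation_error")
  abort_if(!inherits(config, "regression_head_config"),
           "`config` must be a regression_head_config",
           class = "dctdetect_validation_error")
  # clamp the squashing functions away from their limits so the mapping
  # stays strictly inside the open ranges even where the sigmoid/arctan
  # saturate in double precision
  eps <- 1e-12
  s <- min(max(stats::plogis(head$alpha_preact), eps), 1 - eps)
  t <- min(max((2 / pi) * atan(head$beta_preact), -1 + eps), 1 - eps)
  transform_params(config$alpha_max * s, config$beta_max * t)
}

#' Map classification head outputs to transform parameters
#'
#' Takes the expectation of the discrete value grids under the predicted
#' probability vectors:
#' \deqn{\alpha = \sum_k i_\alpha k \, p_\alpha(k), \qquad
#'       \beta = \sum_j i_\beta j \, p_\beta(j).}
#' By convexity the results always lie within the grid ranges.
#'
#' @param head A classification-tagged [classification_head_output()].
#' @param config A [classification_head_config()]; vector lengths must match.
#' @return A [transform_params()] object.
#' @export
classification_transform_params <- function(head,
                                            config = classification_head_config()) {
  abort_if(!inherits(head, "head_output") || head$formulation != "classification",
           "`head` must be a classification-tagged head output",
           class = "dctdetect_formulation_error")
  abort_if(!inherits(config, "classification_head_config"),
           "`config` must be a classification_head_config",
           class = "dctdetect_validation_error")
  v_alpha <- build_alpha_values(config$i_alpha, config$k_max)
  v_beta <- build_beta_values(config$i_beta, config$j_max)
  abort_if(length(head$prob_alpha) != length(v_alpha),
           sprintf("`prob_alpha` has length %d but the config defines %d alpha levels",
                   length(head$prob_alpha), length(v_alpha)),
           class = "dctdetect_validation_error")
  abort_if(length(head$prob_beta) != length(v_beta),
           sprintf("`prob_beta` has length %d but the config defines %d beta levels",
                   length(head$prob_beta), length(v_beta)),
           class = "dctdetect_validation_error")
  transform_params(sum(v_alpha * head$prob_alpha),
                   sum(v_beta * head$prob_beta))
}
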