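#' Encoder specifications for the DCT network
#'
#' The DCT network is an encoder followed by global average pooling and a
#' fully-connected parameter head. Four canonical convolutional feature
#' extractors are provided (their published stage/channel layouts, truncated
#' before the classifier), plus a tiny `toy_linear` encoder for fast,
#' fully-deterministic unit tests and desk-scale training.
#'
#' Final feature channels: `resnet18`/`resnet34` 512, `mobilenet_v2` 1280,
#' `shufflenet_v2` (1.0x) 1024, `toy_linear` 8.
#'
#' @param family One of `"resnet18"`, `"resnet34"`, `"mobilenet_v2"`,
#'   `"shufflenet_v2"`, `"toy_linear"`.
#' @return An `encoder_spec` object with the family name, its final feature
#'   channel count and its minimum input size in pixels.
#' @export
encoder_spec <- function(family = c("resnet18", "resnet34", "mobilenet_v2",
                                    "shufflenet_v2", "toy_linear")) {
  family <- match.arg(family)
  feature_channels <- switch(family,
    resnet18 = 512L, resnet34 = 512L, mobilenet_v2 = 1280L,
    shufflenet_v2 = 1024L, toy_linear = 8L)
  min_input <- if (family == "toy_linear") 1L else 32L
  structure(list(family = family, feature_channels = feature_channels,
                 min_input = min_input),
            class = "encoder_spec")
}

build_encoder <- function(spec) {
  switch(spec$family,
    toy_linear = mk_seq(list(mk_conv(3, 8, 1, pad = 0, bias = TRUE),
                             mk_act("relu"))),
    resnet18 = build_resnet(c(2L, 2L, 2L, 2L)),
    resnet34 = build_resnet(c(3L, 4L, 6L, 3L)),
    mobilenet_v2 = build_mobilenet_v2(),
    shufflenet_v2 = build_shufflenet_v2())
}

build_resnet <- function(blocks_per_stage) {
  channels <- c(64L, 128L, 256L, 512L)
  mods <- list(mk_convbn(3, 64, 7, stride = 2, pad = 3), mk_maxpool())
  cin <- 64L
  for (s in seq_along(channels)) {
    cout <- channels[s]
    for (b in seq_len(blocks_per_stage[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      mods <- c(mods, list(mk_basic_block(cin, cout, stride)))
      cin <- cout
    }
  }
  mk_seq(mods)
}

build_mobilenet_v2 <- function() {
  # (expand factor t, output channels c, repeats n, first stride s)
  cfg <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
              c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  mods <- list(mk_convbn(3, 32, 3, stride = 2, act = "relu6"))
  cin <- 32L
  for (row in cfg) {
    for (b in seq_len(row[3])) {
      stride <- if (b == 1L) row[4] else 1L
      mods <- c(mods, list(mk_inverted_residual(cin, row[2], stride, row[1])))
      cin <- row[2]
    }
  }
  mods <- c(mods, list(mk_convbn(cin, 1280, 1, pad = 0, act = "relu6")))
  mk_seq(mods)
}

build_shufflenet_v2 <- function() {
  stage_channels <- c(116L, 232L, 464L)
  stage_repeats <- c(4L, 8L, 4L)
  mods <- list(mk_convbn(3, 24, 3, stride = 2), mk_maxpool())
  cin <- 24L
  for (s in seq_along(stage_channels)) {
    cout <- stage_channels[s]
    for (b in seq_len(stage_repeats[s])) {
      if (b == 1L) {
        mods <- c(mods, list(mk_shuffle_unit(cin, cout, 2L)))
      } else {
        mods <- c(mods, list(mk_shuffle_unit(cout, cout, 1L)))
      }
    }
    cin <- cout
  }
  mods <- c(mods, list(mk_convbn(cin, 1024, 1, pad = 0)))
  mk_seq(mods)
}

#' Build a DCT network
#'
#' Assembles encoder, global average pooling and a single fully-connected
#' parameter head into a network predicting color transform parameters from
#' an image. The regression head emits 2 pre-activations; the classification
#' head emits `k_max + (2 * j_max + 1)` logits, split into the alpha and
#' beta groups and converted to probabilities by a per-group softmax.
#'
#' Weights are randomly initialized (no pretraining); the build is
#' deterministic given `seed`.
#'
#' @param encoder An [encoder_spec()] or a family name string.
#' @param formulation `"regression"` or `"classification"`.
#' @param head_config A [regression_head_config()] or
#'   [classification_head_config()] matching the formulation; defaults to
#'   the standard configuration for the chosen formulation.
#' @param seed Integer seed for weight initialization.
#' @return A `dct_network` object.
#' @examples
#' net <- build_dct_network("toy_linear", "regression", seed = 1)
#' count_parameters(net)
#' @export
build_dct_network <- function(encoder, formulation = c("regression", "classification"),
                              head_config = NULL, seed = 0L) {
  if (is.character(encoder)) encoder <- encoder_spec(encoder)
  abort_if(!inherits(encoder, "encoder_spec"),
           "`encoder` must be an encoder_spec or a family name",
           class = "dctdetect_config_error")
  formulation <- match.arg(formulation)
  if (is.null(head_config)) {
    head_config <- if (formulation == "regression") regression_head_config()
                   else classification_head_config()
  }
  if (formulation == "regression") {
    abort_if(!inherits(head_config, "regression_head_config"),
             "regression formulation needs a regression_head_config",
             class = "dctdetect_config_error")
    n_out <- 2L
  } else {
    abort_if(!inherits(head_config, "classification_head_config"),
             "classification formulation needs a classification_head_config",
             class = "dctdetect_config_error")
    n_out <- head_config$k_max + 2L * head_config$j_max + 1L
  }
  net <- withr::with_seed(seed, {
    list(encoder = build_encoder(encoder),
         head = mk_linear(encoder$feature_channels, n_out))
  })
  structure(list(spec = encoder, formulation = formulation,
                 head_config = head_config, seed = as.integer(seed),
                 encoder = net$encoder, head = net$head),
            class = "dct_network")
}

#' @export
print.dct_network <- function(x, ...) {
  cat(sprintf("<dct_network> %s encoder (%d feature channels), %s head, %s parameters\n",
              x$spec$family, x$spec$feature_channels, x$formulation,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a DCT network
#'
#' Sums every trainable scalar: convolution and fully-connected weights and
#' biases, and the affine (gamma, beta) pairs of the normalization layers.
#'
#' @param network A `dct_network`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(network) {
  abort_if(!inherits(network, "dct_network"),
           "`network` must be a dct_network",
           class = "dctdetect_validation_error")
  module_param_count(network$encoder) + module_param_count(network$head)
}

#' Raw head output of a DCT network on an image
#'
#' Runs encoder, global average pooling and the fully-connected head, and
#' packages the result as a [regression_head_output()] or
#' [classification_head_output()] depending on the network's formulation.
#'
#' @param network A `dct_network`.
#' @param image RGB image array, at least the encoder's minimum size.
#' @return A `head_output` object.
#' @export
dct_head_output <- function(network, image) {
  validate_image(image)
  d <- dim(image)
  abort_if(d[1] < network$spec$min_input || d[2] < network$spec$min_input,
           sprintf("image (%d x %d) is smaller than the %s encoder minimum (%d x %d)",
                   d[1], d[2], network$spec$family,
                   network$spec$min_input, network$spec$min_input),
           class = "dctdetect_shape_error")
  feats <- module_forward(network$encoder, image)
  pooled <- global_average_pool(feats)
  logits <- as.vector(pooled %*% network$head$params$weight) +
    network$head$params$bias
  if (network$formulation == "regression") {
    regression_head_output(logits[1], logits[2])
  } else {
    k_max <- network$head_config$k_max
    classification_head_output(softmax(logits[seq_len(k_max)]),
                               softmax(logits[-seq_len(k_max)]))
  }
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Predict color transform parameters for an image
#'
#' The full dynamic color transform inference path: encoder features,
#' global average pooling, parameter head, and the formulation's mapping to
#' a bounded `(alpha, beta)` pair. Deterministic for a fixed network.
#'
#' @inheritParams dct_head_output
#' @return A [transform_params()] object.
#' @export
predict_params <- function(network, image) {
  head <- dct_head_output(network, image)
  if (network$formulation == "regression") {
    regression_transform_params(head, network$head_config)
  } else {
    classification_transform_params(head, network$head_config)
  }
}

#' Save or load a DCT network checkpoint
#'
#' Checkpoints are single-file archives (R serialization, format version 1)
#' containing the encoder spec, formulation, head configuration, seed and
#' all weight arrays.
#'
#' @param network A `dct_network`.
#' @param path File path for the checkpoint.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the restored `dct_network`.
#' @export
save_checkpoint <- function(network, path) {
  abort_if(!inherits(network, "dct_network"),
           "`network` must be a dct_network",
           class = "dctdetect_validation_error")
  saveRDS(list(format = "dctdetect_checkpoint", version = 1L,
               network = unclass(network)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  abort_if(!file.exists(path), paste0("checkpoint not found: ", path),
           class = "dctdetect_io_error")
  obj <- readRDS(path)
  abort_if(!identical(obj$format, "dctdetect_checkpoint"),
           paste0("not a dctdetect checkpoint: ", path),
           class = "dctdetect_io_error")
  abort_if(!identical(obj$version, 1L),
           paste0("unsupported checkpoint version: ", obj$version),
           class = "dctdetect_io_error")
  structure(obj$network, class = "dct_network")
}
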