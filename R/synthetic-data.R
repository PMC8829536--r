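#' Synthetic scene configuration
#'
#' Describes the miniature field scenes used throughout the package:
#' a textured background with a handful of brighter elliptical "head"
#' objects whose tight axis-aligned boxes are the annotations. The defaults
#' are desk-scale stand-ins for real phenotyping patches (which are an
#' order of magnitude larger and denser): 128 px frames with 5-12 objects
#' of 10-22 px extent, yellow-ish heads on a green-ish textured canopy.
#'
#' @param height,width Frame size in pixels.
#' @param n_min,n_max Object count range (uniform).
#' @param axis_min,axis_max Semi-axis range of the ellipses, pixels.
#' @param object_color Mean RGB of the objects, normalized units.
#' @param object_jitter Per-object color jitter standard deviation.
#' @param background_color Mean RGB of the background.
#' @param texture_sd Pixelwise Gaussian texture noise amplitude.
#' @return A `scene_config` object.
#' @export
scene_config <- function(height = 128L, width = 128L, n_min = 5L, n_max = 12L,
                         axis_min = 5, axis_max = 11,
                         object_color = c(0.72, 0.62, 0.30),
                         object_jitter = 0.04,
                         background_color = c(0.20, 0.32, 0.16),
                         texture_sd = 0.05) {
  abort_if(!is_number(height) || !is_number(width) || height < 8 || width < 8,
           "frame must be at least 8 x 8 pixels",
           class = "dctdetect_config_error")
  abort_if(!is_number(n_min) || !is_number(n_max) || n_min < 0 || n_max < n_min,
           "need 0 <= n_min <= n_max", class = "dctdetect_config_error")
  abort_if(axis_min <= 0 || axis_max < axis_min,
           "need 0 < axis_min <= axis_max", class = "dctdetect_config_error")
  abort_if(2 * axis_max + 2 >= min(height, width),
           "objects do not fit inside the frame",
           class = "dctdetect_config_error")
  abort_if(any(object_color < 0 | object_color > 1) ||
             any(background_color < 0 | background_color > 1),
           "colors must be within [0, 1]", class = "dctdetect_config_error")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_min = as.integer(n_min), n_max = as.integer(n_max),
                 axis_min = axis_min, axis_max = axis_max,
                 object_color = object_color, object_jitter = object_jitter,
                 background_color = background_color, texture_sd = texture_sd),
            class = "scene_config")
}

#' Per-domain illumination degradation
#'
#' A global linear intensity degradation `x_obs = a * x + b` with known
#' gain and offset, emulating how acquisition conditions shift a whole
#' domain's illumination. It is the inverse problem of the color
#' transform: a transform with `alpha = 1/a`, `beta = -b/a` undoes it
#' exactly (absent clipping).
#'
#' @param a Gain, positive.
#' @param b Offset, normalized intensity units.
#' @param domain Domain label string.
#' @return A `degradation_params` object.
#' @export
degradation_params <- function(a = 1, b = 0, domain = "domain_1") {
  abort_if(!is_number(a) || a <= 0, "`a` must be positive",
           class = "dctdetect_validation_error")
  abort_if(!is_number(b), "`b` must be finite",
           class = "dctdetect_validation_error")
  structure(list(a = a, b = b, domain = as.character(domain)),
            class = "degradation_params")
}

#' Apply an illumination degradation to an image
#'
#' @param image RGB image array.
#' @param deg A [degradation_params()].
#' @param clip Clamp the result to `[0, 1]` (default `TRUE`: real sensors
#'   saturate, which makes exact inversion impossible and the correction
#'   problem realistic). Annotations are unaffected.
#' @return The degraded image.
#' @export
apply_degradation <- function(image, deg, clip = TRUE) {
  validate_image(image)
  abort_if(!inherits(deg, "degradation_params"),
           "`deg` must be a degradation_params",
           class = "dctdetect_validation_error")
  out <- deg$a * image + deg$b
  if (isTRUE(clip)) {
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  out
}

#' Generate one annotated scene
#'
#' Renders the textured background, rejection-samples non-crowded object
#' centers, draws axis-aligned ellipses with per-object color jitter, and
#' returns the image together with the tight bounding box of every object.
#' Fully reproducible given `seed`.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return A list with `image` (H x W x 3 array, values in `[0, 1]`) and
#'   `boxes` (tibble of ground-truth boxes, one row per object).
#' @export
generate_scene <- function(config = scene_config(), seed = 0L) {
  abort_if(!inherits(config, "scene_config"),
           "`config` must be a scene_config", class = "dctdetect_config_error")
  withr::with_seed(seed, {
    h <- config$height; w <- config$width
    img <- array(rep(config$background_color, each = h * w), dim = c(h, w, 3))
    img <- img + array(stats::rnorm(h * w * 3, sd = config$texture_sd),
                       dim = c(h, w, 3))
    n <- if (config$n_max == config$n_min) config$n_min else
      sample(config$n_min:config$n_max, 1)
    boxes <- empty_boxes()
    centers <- matrix(0, 0, 2)
    placed <- 0L
    attempts <- 0L
    xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
    while (placed < n && attempts < 200L * max(1L, n)) {
      attempts <- attempts + 1L
      a <- stats::runif(1, config$axis_min, config$axis_max)
      b <- stats::runif(1, config$axis_min, config$axis_max)
      cx <- stats::runif(1, a + 1, w - a - 1)
      cy <- stats::runif(1, b + 1, h - b - 1)
      # limit crowding: centers at least one max semi-axis apart
      if (nrow(centers) > 0 &&
          min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)) <
            1.2 * config$axis_max) next
      mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
      col <- pmin(pmax(config$object_color +
                         stats::rnorm(3, sd = config$object_jitter), 0), 1)
      shade <- 1 - 0.5 * (((xs - cx) / a)^2 + ((ys - cy) / b)^2)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[mask] <- col[ch] * (0.7 + 0.3 * shade[mask])
        img[, , ch] <- plane
      }
      centers <- rbind(centers, c(cx, cy))
      boxes <- rbind(boxes, tibble::tibble(x_min = cx - a, y_min = cy - b,
                                           x_max = cx + a, y_max = cy + b))
      placed <- placed + 1L
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, boxes = boxes)
  })
}

#' Generate a multi-domain synthetic benchmark
#'
#' Builds per-domain image sets with a known global linear illumination
#' degradation per domain, split into train/validation/test. Both the
#' clean and the degraded image are kept so that parameter-recovery
#' experiments can compare against the known `(a, b)`.
#'
#' @param domains A list; each element is a list with elements `config`
#'   (a [scene_config()]) and `degradation` (a [degradation_params()]).
#' @param images_per_domain Scenes per domain, at least 1.
#' @param split_fractions Named fractions for `train`, `val`, `test`;
#'   must sum to 1.
#' @param seed Integer seed.
#' @param clip Clamp degraded images to `[0, 1]` (default `TRUE`).
#' @return A tibble with one row per image: `image_name`, `domain`,
#'   `split`, list-columns `clean`, `image` (degraded) and `boxes`. The
#'   true degradations are attached as `attr(, "degradations")`, a tibble
#'   of `(domain, a, b)`.
#' @export
generate_benchmark <- function(domains, images_per_domain = 10L,
                               split_fractions = c(train = 0.6, val = 0.2,
                                                   test = 0.2),
                               seed = 0L, clip = TRUE) {
  abort_if(length(domains) < 1, "need at least one domain",
           class = "dctdetect_validation_error")
  abort_if(!is_number(images_per_domain) || images_per_domain < 1,
           "`images_per_domain` must be at least 1",
           class = "dctdetect_validation_error")
  abort_if(abs(sum(split_fractions) - 1) > 1e-8,
           "`split_fractions` must sum to 1",
           class = "dctdetect_validation_error")
  abort_if(!all(c("train", "val", "test") %in% names(split_fractions)),
           "`split_fractions` needs names train, val, test",
           class = "dctdetect_validation_error")
  n <- as.integer(images_per_domain)
  counts <- diff(c(0, round(cumsum(split_fractions[c("train", "val", "test")]) * n)))
  split_vec <- rep(c("train", "val", "test"), times = counts)
  rows <- list()
  degs <- list()
  for (d in seq_along(domains)) {
    cfg <- domains[[d]]$config
    deg <- domains[[d]]$degradation
    abort_if(!inherits(cfg, "scene_config") ||
               !inherits(deg, "degradation_params"),
             "each domain needs a scene_config and a degradation_params",
             class = "dctdetect_validation_error")
    degs[[d]] <- tibble::tibble(domain = deg$domain, a = deg$a, b = deg$b)
    for (i in seq_len(n)) {
      scene_seed <- (seed * 1009L + d * 131L + i) %% .Machine$integer.max
      scene <- generate_scene(cfg, seed = scene_seed)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        image_name = sprintf("%s_%03d.png", deg$domain, i),
        domain = deg$domain,
        split = split_vec[i],
        clean = list(scene$image),
        image = list(apply_degradation(scene$image, deg, clip = clip)),
        boxes = list(scene$boxes))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "degradations") <- dplyr::bind_rows(degs)
  out
}
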