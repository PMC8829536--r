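#' Match detections against ground truth on one image
#'
#' Greedy one-to-one matching, the de-facto standard for detection
#' accuracy: predictions are processed in descending confidence (ties by
#' input order) and each claims the still-unmatched ground-truth box of
#' highest IoU, provided that IoU is strictly above the threshold. Matched
#' pairs are true positives; unmatched truths are false negatives;
#' unmatched predictions are false positives.
#'
#' @param predictions Detection data frame (may be empty); a `confidence`
#'   column orders the greedy pass (missing confidence = input order).
#' @param truths Ground-truth box data frame (may be empty).
#' @param iou_threshold Match threshold in (0, 1); default 0.5.
#' @return A one-row tibble with integer columns `tp`, `fn`, `fp`
#'   satisfying `tp + fn = nrow(truths)` and `tp + fp = nrow(predictions)`.
#' @export
match_detections <- function(predictions, truths, iou_threshold = 0.5) {
  abort_if(!is_number(iou_threshold) || iou_threshold <= 0 || iou_threshold >= 1,
           "`iou_threshold` must be in (0, 1)",
           class = "dctdetect_validation_error")
  if (nrow(predictions) > 0) validate_boxes(predictions, "predictions")
  if (nrow(truths) > 0) validate_boxes(truths, "truths")
  np <- nrow(predictions); nt <- nrow(truths)
  if (np == 0 || nt == 0) {
    return(tibble::tibble(tp = 0L, fn = nt, fp = np))
  }
  conf <- predictions$confidence %||% rep(1, np)
  ord <- order(-conf)
  m <- box_iou_matrix(predictions, truths)
  matched_truth <- logical(nt)
  tp <- 0L
  for (i in ord) {
    ious <- m[i, ]
    ious[matched_truth] <- -1
    best <- which.max(ious)
    if (ious[best] > iou_threshold) {
      matched_truth[best] <- TRUE
      tp <- tp + 1L
    }
  }
  tibble::tibble(tp = tp, fn = nt - tp, fp = np - tp)
}

#' Per-image detection accuracy
#'
#' \deqn{Accuracy = \frac{TP}{TP + FN + FP}}
#' An image with no ground truth and no predictions (all counts zero)
#' scores 1: there was nothing to find and nothing was hallucinated.
#'
#' @param result A one-row data frame or named vector/list with `tp`, `fn`,
#'   `fp` counts.
#' @return Accuracy in `[0, 1]`.
#' @export
image_accuracy <- function(result) {
  tp <- result$tp %||% result["tp"]
  fn <- result$fn %||% result["fn"]
  fp <- result$fp %||% result["fp"]
  counts <- c(tp, fn, fp)
  abort_if(anyNA(counts) || any(counts < 0),
           "`result` needs non-negative tp, fn, fp counts",
           class = "dctdetect_validation_error")
  denom <- sum(counts)
  if (denom == 0) 1 else as.numeric(tp) / denom
}

#' Average Domain Accuracy
#'
#' Two-level unweighted mean of per-image accuracies: images are averaged
#' within their domain, and domain accuracies are averaged across domains.
#' Every domain counts equally regardless of how many images it holds, so
#' the metric rewards robustness across acquisition conditions rather than
#' raw volume.
#'
#' @param per_image A data frame with a `domain` column and either `tp`,
#'   `fn`, `fp` count columns or a precomputed `accuracy` column; one row
#'   per image. An optional `image_id` column is carried through.
#' @return An `eval_report`: list with `per_image` (accuracies added),
#'   `per_domain` (tibble of domain accuracies) and `ada` (scalar).
#'   [generics::tidy()] returns the per-domain table, [generics::glance()]
#'   a one-row summary.
#' @examples
#' ada(data.frame(domain = c("a", "a", "b"),
#'                tp = c(5, 1, 0), fn = c(0, 1, 0), fp = c(0, 1, 0)))$ada
#' @export
ada <- function(per_image) {
  abort_if(!is.data.frame(per_image) || nrow(per_image) == 0,
           "`per_image` must be a non-empty data frame",
           class = "dctdetect_validation_error")
  abort_if(!"domain" %in% names(per_image) || anyNA(per_image$domain),
           "every image needs a domain label",
           class = "dctdetect_validation_error")
  per_image <- tibble::as_tibble(per_image)
  if (!"accuracy" %in% names(per_image)) {
    abort_if(!all(c("tp", "fn", "fp") %in% names(per_image)),
             "`per_image` needs tp/fn/fp counts or an accuracy column",
             class = "dctdetect_validation_error")
    per_image$accuracy <- vapply(seq_len(nrow(per_image)), function(i) {
      image_accuracy(per_image[i, ])
    }, numeric(1))
  }
  per_domain <- per_image |>
    dplyr::group_by(domain = .data$domain) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     n_images = dplyr::n(), .groups = "drop")
  structure(list(per_image = per_image, per_domain = per_domain,
                 ada = mean(per_domain$accuracy)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> ADA = %.4f over %d domain(s), %d image(s)\n",
              x$ada, nrow(x$per_domain), nrow(x$per_image)))
  print(x$per_domain)
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$per_domain

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(ada = x$ada, n_domains = nrow(x$per_domain),
                 n_images = nrow(x$per_image),
                 tp = sum(x$per_image$tp %||% NA),
                 fn = sum(x$per_image$fn %||% NA),
                 fp = sum(x$per_image$fp %||% NA))
}

#' Evaluate a detector on a multi-domain dataset
#'
#' Runs the detector on every image — optionally through a color transform
#' — matches detections against ground truth, and aggregates the Average
#' Domain Accuracy.
#'
#' @param detector A detector (see [detect()]).
#' @param dataset Data frame with list-columns `image`, `boxes` and a
#'   `domain` column.
#' @param transform `NULL` for no transform, a [transform_params()] applied
#'   globally, a `dct_network` predicting per-image parameters, or a
#'   function `image -> transform_params`.
#' @param clip Clamp transformed images to `[0, 1]` before detection.
#' @param iou_threshold Match threshold for [match_detections()].
#' @param ... Passed to [detect()].
#' @return An `eval_report` (see [ada()]).
#' @export
evaluate_detector <- function(detector, dataset, transform = NULL,
                              clip = FALSE, iou_threshold = 0.5, ...) {
  validate_dataset(dataset)
  abort_if(!"domain" %in% names(dataset),
           "`dataset` needs a `domain` column",
           class = "dctdetect_validation_error")
  n <- nrow(dataset)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    img <- dataset$image[[i]]
    if (!is.null(transform)) {
      tp <- if (inherits(transform, "transform_params")) transform
            else if (inherits(transform, "dct_network")) predict_params(transform, img)
            else if (is.function(transform)) transform(img)
            else rlang::abort("unsupported `transform`", class = "dctdetect_validation_error")
      img <- apply_color_transform(img, tp, clip = clip)
    }
    det <- detect(detector, img, ...)
    res <- match_detections(det, dataset$boxes[[i]], iou_threshold)
    res$domain <- dataset$domain[i]
    res$image_id <- if ("image_name" %in% names(dataset)) dataset$image_name[i] else i
    rows[[i]] <- res
  }
  ada(dplyr::bind_rows(rows))
}
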