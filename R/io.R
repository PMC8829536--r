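# File formats: a simple box CSV dialect, COCO-style JSON for
# interoperability, prediction files, dataset manifests and PNG images.
#
# Box CSV dialect: columns image_name, domain, boxes; the boxes field is a
# semicolon-separated list of "x_min y_min x_max y_max" quadruples in
# pixels, 0-based. An empty boxes field means an image with no objects.

format_boxes_field <- function(boxes) {
  if (nrow(boxes) == 0) return("")
  paste(sprintf("%.6f %.6f %.6f %.6f", boxes$x_min, boxes$y_min,
                boxes$x_max, boxes$y_max), collapse = ";")
}

parse_boxes_field <- function(s, line = NA) {
  if (is.na(s) || !nzchar(trimws(s))) return(empty_boxes())
  parts <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  vals <- lapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(p), "\\s+")[[1]]))
    abort_if(length(v) != 4L || anyNA(v),
             sprintf("malformed box string %s on line %s", dQuote(p),
                     ifelse(is.na(line), "?", line)),
             class = "dctdetect_parse_error")
    v
  })
  m <- do.call(rbind, vals)
  boxes <- tibble::tibble(x_min = m[, 1], y_min = m[, 2],
                          x_max = m[, 3], y_max = m[, 4])
  validate_boxes(boxes)
  boxes
}

#' Read bounding-box annotations
#'
#' @param path File path.
#' @param dialect `"box_csv"` (the package's CSV dialect: columns
#'   `image_name`, `domain`, `boxes` with semicolon-separated
#'   `"x_min y_min x_max y_max"` quadruples) or `"coco_json"` (COCO-style
#'   JSON; its 1-indexed ids and `[x, y, width, height]` boxes are
#'   converted at this boundary).
#' @return A tibble with columns `image_name`, `domain` and a list-column
#'   `boxes`.
#' @export
read_annotations <- function(path, dialect = c("box_csv", "coco_json")) {
  dialect <- match.arg(dialect)
  abort_if(!file.exists(path), paste0("file not found: ", path),
           class = "dctdetect_io_error")
  if (dialect == "box_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    abort_if(!all(c("image_name", "domain", "boxes") %in% names(df)),
             "box_csv needs columns image_name, domain, boxes",
             class = "dctdetect_parse_error")
    boxes <- lapply(seq_len(nrow(df)), function(i) {
      parse_boxes_field(df$boxes[i], line = i + 1L)
    })
    tibble::tibble(image_name = df$image_name, domain = df$domain,
                   boxes = boxes)
  } else {
    obj <- jsonlite::read_json(path)
    imgs <- obj$images
    anns <- obj$annotations
    by_img <- split(anns, vapply(anns, function(a) a$image_id, numeric(1)))
    rows <- lapply(imgs, function(im) {
      aa <- by_img[[as.character(im$id)]]
      boxes <- if (is.null(aa)) empty_boxes() else {
        m <- t(vapply(aa, function(a) as.numeric(unlist(a$bbox)), numeric(4)))
        tibble::tibble(x_min = m[, 1], y_min = m[, 2],
                       x_max = m[, 1] + m[, 3], y_max = m[, 2] + m[, 4])
      }
      tibble::tibble(image_name = im$file_name,
                     domain = im$domain %||% "default", boxes = list(boxes))
    })
    dplyr::bind_rows(rows)
  }
}

#' Write bounding-box annotations
#'
#' @param records A data frame with `image_name`, `domain` and a `boxes`
#'   list-column.
#' @inheritParams read_annotations
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path, dialect = c("box_csv", "coco_json")) {
  dialect <- match.arg(dialect)
  if (dialect == "box_csv") {
    lines <- c("image_name,domain,boxes",
               vapply(seq_len(nrow(records)), function(i) {
                 sprintf("%s,%s,%s", records$image_name[i], records$domain[i],
                         format_boxes_field(records$boxes[[i]]))
               }, character(1)))
    writeLines(lines, path)
  } else {
    ann_id <- 0L
    images <- list(); annotations <- list()
    for (i in seq_len(nrow(records))) {
      images[[i]] <- list(id = i, file_name = records$image_name[i],
                          domain = records$domain[i])
      b <- records$boxes[[i]]
      for (j in seq_len(nrow(b))) {
        ann_id <- ann_id + 1L
        annotations[[ann_id]] <- list(
          id = ann_id, image_id = i, category_id = 1L,
          bbox = c(b$x_min[j], b$y_min[j],
                   b$x_max[j] - b$x_min[j], b$y_max[j] - b$y_min[j]))
      }
    }
    jsonlite::write_json(
      list(images = images, annotations = annotations,
           categories = list(list(id = 1L, name = "head"))),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write detection predictions
#'
#' CSV with columns `image_name`, `x_min`, `y_min`, `x_max`, `y_max`,
#' `confidence`; confidences serialized with 6 decimal places; rows ordered
#' by image name, then descending confidence, so two writes of the same
#' input are byte-identical.
#'
#' @param predictions Either a data frame with an `image_name` column and
#'   detection columns, or a named list of per-image detection data frames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  df <- normalize_predictions(predictions)
  df <- df[order(df$image_name, -df$confidence), ]
  lines <- c("image_name,x_min,y_min,x_max,y_max,confidence",
             sprintf("%s,%g,%g,%g,%g,%.6f", df$image_name, df$x_min,
                     df$y_min, df$x_max, df$y_max, df$confidence))
  writeLines(lines, path)
  invisible(path)
}

normalize_predictions <- function(predictions) {
  if (is.data.frame(predictions)) {
    abort_if(!"image_name" %in% names(predictions),
             "predictions data frame needs an `image_name` column",
             class = "dctdetect_validation_error")
    return(predictions)
  }
  abort_if(length(predictions) > 0 && is.null(names(predictions)),
           "per-image prediction lists must be named by image",
           class = "dctdetect_validation_error")
  rows <- lapply(names(predictions), function(nm) {
    d <- predictions[[nm]]
    if (nrow(d) == 0) return(NULL)
    d$image_name <- nm
    d
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- empty_detections()
    out$image_name <- character()
  }
  out
}

#' Read detection predictions
#'
#' @param path Prediction CSV written by [write_predictions()].
#' @return A tibble with `image_name`, box columns and `confidence`.
#' @export
read_predictions <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path),
           class = "dctdetect_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Write or read a benchmark dataset directory
#'
#' The on-disk layout is plain text plus PNG: `manifest.csv` in the box CSV
#' dialect extended with a `split` column, `images/` (degraded images as
#' PNG), `clean/` (pre-degradation images), and `degradations.csv` holding
#' the true per-domain `(a, b)` for parameter-recovery experiments.
#'
#' @param dataset A benchmark tibble from [generate_benchmark()].
#' @param dir Target directory (created if needed).
#' @return `dir` (write) or the reconstructed dataset tibble (read).
#' @export
write_benchmark <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "clean"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(dataset))) {
    png::writePNG(dataset$image[[i]],
                  file.path(dir, "images", dataset$image_name[i]))
    if ("clean" %in% names(dataset)) {
      png::writePNG(dataset$clean[[i]],
                    file.path(dir, "clean", dataset$image_name[i]))
    }
  }
  lines <- c("image_name,domain,split,boxes",
             vapply(seq_len(nrow(dataset)), function(i) {
               sprintf("%s,%s,%s,%s", dataset$image_name[i],
                       dataset$domain[i], dataset$split[i],
                       format_boxes_field(dataset$boxes[[i]]))
             }, character(1)))
  writeLines(lines, file.path(dir, "manifest.csv"))
  degs <- attr(dataset, "degradations")
  if (!is.null(degs)) {
    utils::write.csv(degs, file.path(dir, "degradations.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  abort_if(!file.exists(manifest_path),
           paste0("missing manifest: ", manifest_path),
           class = "dctdetect_io_error")
  df <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  read_png3 <- function(path) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  }
  out <- tibble::tibble(
    image_name = df$image_name, domain = df$domain, split = df$split,
    image = lapply(file.path(dir, "images", df$image_name), read_png3),
    boxes = lapply(seq_len(nrow(df)), function(i) {
      parse_boxes_field(df$boxes[i], line = i + 1L)
    }))
  clean_paths <- file.path(dir, "clean", df$image_name)
  if (all(file.exists(clean_paths))) {
    out$clean <- lapply(clean_paths, read_png3)
  }
  deg_path <- file.path(dir, "degradations.csv")
  if (file.exists(deg_path)) {
    attr(out, "degradations") <- tibble::as_tibble(
      utils::read.csv(deg_path, stringsAsFactors = FALSE))
  }
  out
}

#' Export an evaluation report
#'
#' Writes a human-readable per-domain table with the ADA plus a
#' machine-readable YAML key/value file (`<path>.yaml`).
#'
#' @param report An `eval_report` from [ada()] / [evaluate_detector()].
#' @param path Text file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  abort_if(!inherits(report, "eval_report"),
           "`report` must be an eval_report",
           class = "dctdetect_validation_error")
  lines <- c("domain\taccuracy\tn_images",
             sprintf("%s\t%.6f\t%d", report$per_domain$domain,
                     report$per_domain$accuracy, report$per_domain$n_images),
             sprintf("ADA\t%.6f\t%d", report$ada,
                     sum(report$per_domain$n_images)))
  writeLines(lines, path)
  yaml::write_yaml(
    list(ada = report$ada,
         domains = stats::setNames(as.list(report$per_domain$accuracy),
                                   report$per_domain$domain)),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Write or read a training configuration
#'
#' YAML round-trip of a [train_config()].
#'
#' @param config A `train_config`.
#' @param path YAML file path.
#' @return `path` (write) or the reconstructed `train_config` (read).
#' @export
write_train_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_train_config
#' @export
read_train_config <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path),
           class = "dctdetect_io_error")
  do.call(train_config, yaml::read_yaml(path))
}
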