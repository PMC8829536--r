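boxed <- function(x, y, size = 10, conf = 0.9) {
  tibble::tibble(x_min = x, y_min = y, x_max = x + size, y_max = y + size,
                 confidence = conf, class_label = 0L)
}

test_that("three agreeing boxes fuse into one averaged detection", {
  sets <- list(prediction_set(1, boxed(10, 10, conf = 0.9)),
               prediction_set(2, boxed(11, 10, conf = 0.8)),
               prediction_set(3, boxed(10, 11, conf = 0.7)))
  fused <- vme_fuse(sets, vme_config(0.6))
  expect_equal(nrow(fused), 1)
  expect_equal(fused$x_min, mean(c(10, 11, 10)))
  expect_equal(fused$y_min, mean(c(10, 10, 11)))
  expect_equal(fused$confidence, mean(c(0.9, 0.8, 0.7)))
})

test_that("a lone box among K=3 models is discarded", {
  sets <- list(prediction_set(1, boxed(10, 10)),
               prediction_set(2, boxed(70, 70)),
               prediction_set(3, boxed(70.5, 70)))
  fused <- vme_fuse(sets, vme_config(0.6))
  # the two agreeing boxes survive; the lone one (count 1 <= floor(3/2)) dies
  expect_equal(nrow(fused), 1)
  expect_gt(fused$x_min, 50)
})

test_that("a single model passes through unchanged", {
  b <- dplyr::bind_rows(boxed(5, 5, conf = 0.9), boxed(40, 40, conf = 0.4))
  fused <- vme_fuse(list(prediction_set(1, b)), vme_config(0.6))
  expect_equal(nrow(fused), 2)
  expect_equal(fused[dctdetect:::box_cols], b[dctdetect:::box_cols])
})

test_that("K identical sets collapse to the original boxes", {
  b <- dplyr::bind_rows(boxed(5, 5, conf = 0.9), boxed(40, 40, conf = 0.4))
  sets <- lapply(1:3, function(i) prediction_set(i, b))
  fused <- vme_fuse(sets, vme_config(0.6))
  expect_equal(nrow(fused), 2)
  expect_equal(fused$x_min, b$x_min)
  expect_equal(fused$confidence, b$confidence)
})

test_that("empty ensembles are rejected, empty sets allowed", {
  expect_error(vme_fuse(list()), class = "dctdetect_validation_error")
  empty <- lapply(1:3, function(i) prediction_set(i, boxed(1, 1)[0, ]))
  expect_equal(nrow(vme_fuse(empty)), 0)
  expect_equal(nrow(vme_fuse_oracle(empty)), 0)
})

test_that("fusion matches the exhaustive oracle on random instances", {
  set.seed(61)
  for (rep in 1:300) {
    k <- sample(1:5, 1)
    sets <- random_prediction_sets(k, max_boxes = 8)
    tau <- runif(1, 0.3, 0.8)
    a <- vme_fuse(sets, vme_config(tau))
    b <- vme_fuse_oracle(sets, vme_config(tau))
    expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-9)
  }
})

test_that("fusion is invariant to permuting sets and boxes", {
  set.seed(62)
  for (rep in 1:30) {
    sets <- random_prediction_sets(3, max_boxes = 10)
    base <- vme_fuse(sets, vme_config(0.5))
    perm <- sets[sample(3)]
    # renumber sources positionally but keep content identity
    perm <- lapply(seq_along(perm), function(i) {
      s <- perm[[i]]
      s <- s[sample(nrow(s)), , drop = FALSE]
      s$source <- i
      s
    })
    shuffled <- vme_fuse(perm, vme_config(0.5))
    key <- function(d) d[order(d$x_min, d$y_min, d$confidence), ]
    expect_equal(as.data.frame(key(base)), as.data.frame(key(shuffled)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("raising tau never keeps more clusters", {
  set.seed(63)
  for (rep in 1:30) {
    sets <- random_prediction_sets(3, max_boxes = 10)
    kept <- vapply(c(0.3, 0.5, 0.7, 0.9), function(tau) {
      nrow(vme_fuse(sets, vme_config(tau)))
    }, numeric(1))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("fused coordinates lie within their cluster hull", {
  set.seed(64)
  for (rep in 1:30) {
    sets <- random_prediction_sets(3, max_boxes = 6)
    pooled <- dplyr::bind_rows(sets)
    fused <- vme_fuse(sets, vme_config(0.4))
    for (i in seq_len(nrow(fused))) {
      expect_gte(fused$x_min[i], min(pooled$x_min) - 1e-9)
      expect_lte(fused$x_max[i], max(pooled$x_max) + 1e-9)
      expect_gte(fused$y_min[i], min(pooled$y_min) - 1e-9)
      expect_lte(fused$y_max[i], max(pooled$y_max) + 1e-9)
    }
  }
})

test_that("test-time augmentation inverts box coordinates exactly", {
  # a detector stub that reports the bounding box of bright pixels
  blob_detector <- function(image, ...) {
    bright <- which(image[, , 1] > 0.9, arr.ind = TRUE)
    tibble::tibble(x_min = min(bright[, 2]) - 1, y_min = min(bright[, 1]) - 1,
                   x_max = max(bright[, 2]), y_max = max(bright[, 1]),
                   confidence = 1, class_label = 0L)
  }
  img <- array(0, dim = c(20, 30, 3))  # non-square on purpose
  img[5:8, 12:17, ] <- 1               # blob rows 5-8, cols 12-17
  truth <- c(11, 4, 17, 8)
  sets <- tta_predict(blob_detector, img,
                      c("identity", "flip_lr", "flip_ud",
                        "rot90", "rot180", "rot270"))
  expect_length(sets, 6)
  for (s in sets) {
    expect_equal(unname(unlist(s[1, dctdetect:::box_cols])), truth,
                 tolerance = 1e-9)
  }
  expect_error(tta_predict(blob_detector, img, "swirl"),
               class = "dctdetect_config_error")
})

test_that("identity-only TTA equals direct detection", {
  det <- fixture_detector()
  img <- generate_scene(scene_config(), seed = 99)$image
  direct <- detect(det, img)
  sets <- tta_predict(det, img, "identity")
  expect_length(sets, 1)
  expect_equal(as.data.frame(sets[[1]][names(direct)]), as.data.frame(direct))
  # K = 1 fusion returns them unchanged
  fused <- vme_fuse(sets)
  expect_equal(nrow(fused), nrow(direct))
})

test_that("flip TTA on a symmetric detector agrees with direct boxes", {
  det <- fixture_detector()
  img <- generate_scene(scene_config(), seed = 100)$image
  direct <- detect(det, img)
  flipped <- tta_predict(det, img, "flip_lr")[[1]]
  # mapped-back boxes should mostly coincide with direct detections
  if (nrow(direct) > 0 && nrow(flipped) > 0) {
    m <- dctdetect:::box_iou_matrix(direct, flipped)
    expect_gt(max(m), 0.7)
  }
})
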