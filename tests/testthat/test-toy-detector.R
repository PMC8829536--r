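test_that("iou matches hand-computed overlaps", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 2), c(1, 0, 3, 2)),
               class = "dctdetect_validation_error")
})

test_that("giou matches hand-computed values", {
  expect_equal(giou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  # touching boxes: union fills the hull, IoU = 0
  expect_equal(giou(c(0, 0, 1, 1), c(1, 0, 2, 1)), 0)
  # far apart: enclosure 100, union 2
  expect_equal(giou(c(0, 0, 1, 1), c(9, 9, 10, 10)), -0.98)
  # containment: enclosing hull equals the union, so giou equals iou
  a <- c(1, 1, 5, 5); b <- c(2, 2, 3, 4)
  expect_equal(giou(a, b), iou(a, b))
})

test_that("iou and giou are symmetric, translation-invariant, and ordered", {
  set.seed(52)
  for (i in 1:50) {
    a <- unlist(random_boxes(1)[1, ])
    b <- unlist(random_boxes(1)[1, ])
    expect_equal(iou(a, b), iou(b, a))
    expect_equal(giou(a, b), giou(b, a))
    shift <- runif(2, -30, 30)
    expect_equal(iou(a + shift[c(1, 2, 1, 2)], b + shift[c(1, 2, 1, 2)]),
                 iou(a, b), tolerance = 1e-12)
    expect_equal(giou(a + shift[c(1, 2, 1, 2)], b + shift[c(1, 2, 1, 2)]),
                 giou(a, b), tolerance = 1e-12)
    expect_lte(giou(a, b), iou(a, b) + 1e-12)
    expect_gt(giou(a, b), -1)
    expect_lte(giou(a, b), 1)
  }
})

test_that("giou agrees with a rasterized counting oracle on grid-aligned boxes", {
  # integer-coordinate boxes make unit-cell counting exact
  count_cells <- function(box, predicate_frame = 40) {
    xs <- seq_len(predicate_frame) - 0.5
    mask <- outer(xs > box[2] & xs < box[4], xs > box[1] & xs < box[3], "&")
    sum(mask)
  }
  set.seed(53)
  for (i in 1:100) {
    a <- sort(sample(0:30, 2)); a2 <- sort(sample(0:30, 2))
    b <- sort(sample(0:30, 2)); b2 <- sort(sample(0:30, 2))
    if (a[1] == a[2] || a2[1] == a2[2] || b[1] == b[2] || b2[1] == b2[2]) next
    boxa <- c(a[1], a2[1], a[2], a2[2])
    boxb <- c(b[1], b2[1], b[2], b2[2])
    area_a <- count_cells(boxa); area_b <- count_cells(boxb)
    inter <- count_cells(c(pmax(boxa[1:2], boxb[1:2]), pmin(boxa[3:4], boxb[3:4])))
    if (boxa[1] >= boxb[3] || boxb[1] >= boxa[3] ||
        boxa[2] >= boxb[4] || boxb[2] >= boxa[4]) inter <- 0
    union <- area_a + area_b - inter
    hull <- count_cells(c(pmin(boxa[1:2], boxb[1:2]), pmax(boxa[3:4], boxb[3:4])))
    expect_equal(iou(boxa, boxb), inter / union, tolerance = 1e-9)
    expect_equal(giou(boxa, boxb), inter / union - (hull - union) / hull,
                 tolerance = 1e-9)
  }
})

test_that("detection loss separates classification and localization terms", {
  boxes <- tibble::tibble(x_min = c(2, 20), y_min = c(2, 20),
                          x_max = c(10, 30), y_max = c(10, 30))
  positive <- c(TRUE, FALSE, TRUE, FALSE)
  # perfect predictions: exact boxes, objectness 1 at positives, 0 elsewhere
  perfect <- list(objectness = c(1, 0, 1, 0),
                  boxes = boxes[c(1, 1, 2, 2), ])
  loss <- detection_loss(perfect, list(positive = positive, boxes = boxes))
  expect_equal(unname(loss["loss_loc"]), 0)
  expect_lt(loss["loss_cls"], 1e-9)

  # no ground truth, all objectness 0: nothing to penalize
  silent <- list(objectness = rep(0, 4), boxes = boxes[c(1, 1, 2, 2), ])
  loss0 <- detection_loss(silent, list(positive = rep(FALSE, 4),
                                       boxes = boxes[0, ]))
  expect_lt(sum(loss0), 1e-9)

  # a positive with zero-overlap prediction: loss_loc = 1 - giou (oracle)
  shifted <- boxes[1, ] + 50
  one <- list(objectness = c(1, 0, 0, 0),
              boxes = dplyr::bind_rows(shifted, boxes[c(1, 2, 2), ]))
  loss1 <- detection_loss(one, list(positive = c(TRUE, FALSE, FALSE, FALSE),
                                    boxes = boxes[1, ]))
  expect_equal(unname(loss1["loss_loc"]),
               1 - giou(shifted, boxes[1, ]))
  expect_error(detection_loss(list(objectness = numeric(), boxes = boxes[0, ]),
                              list(positive = logical(), boxes = boxes[0, ])),
               class = "dctdetect_validation_error")
})

test_that("an untrained zero-logit detector emits nothing at threshold 0.5", {
  m <- toy_detector(seed = 1)
  m$params$w1[] <- 0; m$params$b1[] <- 0
  m$params$w2[] <- 0; m$params$b2[] <- 0
  det <- toy_detect(m, flat_image(64, 64), confidence_threshold = 0.5)
  expect_equal(nrow(det), 0)
  # and detection fails below one grid cell
  expect_error(toy_detect(m, flat_image(8, 8)),
               class = "dctdetect_shape_error")
})

test_that("duplicate candidates collapse under non-maximum suppression", {
  b <- tibble::tibble(x_min = c(10, 10, 40), y_min = c(10, 10, 40),
                      x_max = c(20, 20, 50), y_max = c(20, 20, 50),
                      confidence = c(0.9, 0.8, 0.7))
  keep <- dctdetect:::nms_keep(b, 0.5)
  expect_equal(keep, c(1L, 3L))
})

test_that("hand-derived detector gradients match finite differences", {
  scene <- generate_scene(small_scene_config(), seed = 5)
  m <- toy_detector(seed = 2)
  res <- dctdetect:::detector_loss_grad(m, scene$image, scene$boxes)
  expect_gt(res$n_pos, 0)
  h <- 1e-6
  set.seed(54)
  for (nm in c("w1", "b1", "w2", "b2")) {
    idx <- sample(length(m$params[[nm]]), 2)
    for (i in idx) {
      mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
      mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
      rp <- dctdetect:::detector_loss_grad(mp, scene$image, scene$boxes)
      rm_ <- dctdetect:::detector_loss_grad(mm, scene$image, scene$boxes)
      numeric_grad <- ((rp$loss_cls + rp$loss_loc) -
                         (rm_$loss_cls + rm_$loss_loc)) / (2 * h)
      expect_equal(res$grads[[nm]][i], numeric_grad, tolerance = 1e-4)
    }
  }
})

test_that("a trained detector finds synthetic objects", {
  det <- fixture_detector()
  scene <- generate_scene(scene_config(), seed = 1001)
  found <- detect(det, scene$image)
  expect_gt(nrow(found), 0)
  expect_true(all(diff(found$confidence) <= 0))
  expect_true(all(found$confidence > 0.5))
  res <- match_detections(found, scene$boxes)
  expect_gt(res$tp, 0)
})
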