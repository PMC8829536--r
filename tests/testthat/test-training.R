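test_that("detector training reduces the loss and is seed-reproducible", {
  ds <- scene_dataset(1:10, config = small_scene_config())
  cfg <- train_config(epochs_detector = 6, seed = 3)
  fit1 <- train_detector(ds, cfg)
  fit2 <- train_detector(ds, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
  total <- fit1$history$loss_cls + fit1$history$loss_loc
  expect_lt(mean(utils::tail(total, 3)), mean(utils::head(total, 3)))
  expect_error(train_detector(ds[0, ], cfg),
               class = "dctdetect_validation_error")
})

test_that("a dataset without boxes trains objectness only", {
  ds <- scene_dataset(1:4, config = small_scene_config())
  ds$boxes <- lapply(ds$boxes, function(b) b[0, ])
  fit <- train_detector(ds, train_config(epochs_detector = 3, seed = 1))
  expect_true(all(fit$history$loss_loc == 0))
  expect_gt(nrow(fit$history), 0)
})

test_that("the frozen detector is bit-identical after transform training", {
  det <- freeze_detector(fixture_detector())
  before <- det$params
  ds <- scene_dataset(61:66, domain = "d", config = small_scene_config(),
                      deg = degradation_params(0.7, 0, "d"))
  dct <- build_dct_network("toy_linear", "regression", seed = 1)
  fit <- train_dct(ds, det, dct, train_config(epochs_dct = 2, seed = 1))
  expect_identical(det$params, before)
  expect_s3_class(fit$network, "dct_network")
  expect_false(identical(fit$network$head$params$weight,
                         dct$head$params$weight))
})

test_that("transform training enforces its contracts", {
  ds <- scene_dataset(1:2, config = small_scene_config())
  dct <- build_dct_network("toy_linear", "regression", seed = 1)
  unfrozen <- fixture_detector()
  expect_error(train_dct(ds, unfrozen, dct, train_config()),
               class = "dctdetect_contract_error")
  big <- build_dct_network("resnet18", "regression", seed = 1)
  expect_error(train_dct(ds, freeze_detector(unfrozen), big, train_config()),
               class = "dctdetect_config_error")
})

test_that("transform-network gradients match finite differences", {
  scene <- generate_scene(small_scene_config(), seed = 9)
  det <- freeze_detector(toy_detector(seed = 4))
  for (formulation in c("regression", "classification")) {
    dct <- build_dct_network("toy_linear", formulation, seed = 6)
    params <- list(enc_w = dct$encoder$children[[1]]$params$weight,
                   enc_b = dct$encoder$children[[1]]$params$bias,
                   head_w = dct$head$params$weight,
                   head_b = dct$head$params$bias)
    g <- dctdetect:::dct_grad_step(params, dct, det, scene$image, scene$boxes)
    h <- 1e-5
    set.seed(55)
    for (nm in names(params)) {
      i <- sample(length(params[[nm]]), 1)
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      rp <- dctdetect:::dct_grad_step(pp, dct, det, scene$image, scene$boxes)
      rm_ <- dctdetect:::dct_grad_step(pm, dct, det, scene$image, scene$boxes)
      numeric_grad <- ((rp$loss_cls + rp$loss_loc) -
                         (rm_$loss_cls + rm_$loss_loc)) / (2 * h)
      expect_equal(g$grads[[nm]][i], numeric_grad, tolerance = 1e-3)
    }
  }
})

test_that("transform training on an identity domain does not hurt", {
  det <- freeze_detector(fixture_detector())
  ds <- scene_dataset(71:78, domain = "clean")
  base <- evaluate_detector(det, ds)
  dct <- build_dct_network("toy_linear", "regression", seed = 2)
  fit <- train_dct(ds, det, dct, train_config(epochs_dct = 8, seed = 2))
  with_dct <- evaluate_detector(det, ds, transform = fit$network)
  expect_gte(with_dct$ada, base$ada - 0.1)
  # the learned gain stays near 1 when there is nothing to correct
  alphas <- vapply(ds$image, function(im) predict_params(fit$network, im)$alpha,
                   numeric(1))
  expect_lt(abs(mean(alphas) - 1), 0.25)
})

test_that("the color sweep reproduces the baseline at the identity point", {
  det <- fixture_detector()
  ds <- scene_dataset(81:86, domain = "d",
                      deg = degradation_params(0.8, 0.02, "d"))
  base <- evaluate_detector(det, ds)
  sweep_tab <- color_sweep(det, ds, alpha_grid = c(1), beta_grid = c(0))
  expect_identical(sweep_tab$ada, base$ada)
  # composability: concatenated grids give the union of rows
  s1 <- color_sweep(det, ds, alpha_grid = c(0.8, 1.2), beta_grid = 0)
  s2 <- color_sweep(det, ds, alpha_grid = c(1.6), beta_grid = 0)
  s12 <- color_sweep(det, ds, alpha_grid = c(0.8, 1.2, 1.6), beta_grid = 0)
  expect_equal(as.data.frame(dplyr::bind_rows(s1, s2)), as.data.frame(s12))
  expect_error(color_sweep(det, ds, numeric(), 0),
               class = "dctdetect_validation_error")
})

test_that("pseudolabels mirror detector output and are monotone in threshold", {
  det <- fixture_detector()
  imgs <- lapply(91:93, function(i) generate_scene(scene_config(), seed = i)$image)
  none <- make_pseudolabels(function(image, ...) dctdetect:::empty_detections(),
                            imgs)
  expect_true(all(vapply(none$boxes, nrow, integer(1)) == 0))
  expect_true(all(none$pseudo))

  lo <- make_pseudolabels(det, imgs, confidence_threshold = 0)
  hi <- make_pseudolabels(det, imgs, confidence_threshold = 1)
  mid <- make_pseudolabels(det, imgs, confidence_threshold = 0.5)
  for (i in seq_along(imgs)) {
    expect_lte(nrow(hi$boxes[[i]]), nrow(mid$boxes[[i]]))
    expect_lte(nrow(mid$boxes[[i]]), nrow(lo$boxes[[i]]))
    direct <- toy_detect(det, imgs[[i]], confidence_threshold = 0.5)
    expect_equal(nrow(mid$boxes[[i]]), nrow(direct))
  }
})

test_that("train configs round-trip through YAML", {
  cfg <- train_config(epochs_detector = 5, lr_detector = 0.07,
                      augment_color_jitter = TRUE, seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_train_config(cfg, path)
  expect_equal(read_train_config(path), cfg)
})
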