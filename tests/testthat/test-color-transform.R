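test_that("the linear transform scales and shifts all channels identically", {
  img <- flat_image(value = 0.5)
  out <- apply_color_transform(img, transform_params(0.7, 0))
  expect_equal(out[1, 1, ], rep(0.35, 3))

  jitter <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  out2 <- apply_color_transform(jitter, transform_params(1.3, -0.2))
  expect_equal(out2, 1.3 * jitter - 0.2)
})

test_that("the identity transform is bit-identical to the input", {
  set.seed(11)
  for (dims in list(c(1, 1), c(5, 9), c(16, 16))) {
    img <- array(runif(prod(dims) * 3), dim = c(dims, 3))
    expect_identical(apply_color_transform(img, transform_params(1, 0)), img)
  }
})

test_that("clipping clamps to [0, 1]", {
  img <- flat_image(value = 0.6)
  out <- apply_color_transform(img, transform_params(2, 0.1), clip = TRUE)
  expect_equal(out[2, 2, 1], 1.0)
  out_lo <- apply_color_transform(flat_image(value = 0.1),
                                  transform_params(0.5, -0.3), clip = TRUE)
  expect_equal(out_lo[1, 1, 1], 0)
  unclipped <- apply_color_transform(img, transform_params(2, 0.1))
  expect_equal(unclipped[1, 1, 1], 1.3)
})

test_that("transform application rejects bad inputs", {
  expect_error(apply_color_transform(array(1, dim = c(4, 4, 2)),
                                     transform_params(1, 0)),
               class = "dctdetect_shape_error")
  expect_error(transform_params(0, 0), class = "dctdetect_validation_error")
  expect_error(transform_params(-1, 0), class = "dctdetect_validation_error")
  expect_error(transform_params(Inf, 0), class = "dctdetect_validation_error")
  expect_error(transform_params(1, NaN), class = "dctdetect_validation_error")
})

test_that("two transforms compose into one linear transform", {
  set.seed(21)
  for (i in 1:20) {
    img <- array(runif(6 * 7 * 3), dim = c(6, 7, 3))
    p1 <- transform_params(runif(1, 0.2, 2), runif(1, -0.3, 0.3))
    p2 <- transform_params(runif(1, 0.2, 2), runif(1, -0.3, 0.3))
    two_step <- apply_color_transform(apply_color_transform(img, p1), p2)
    one_step <- apply_color_transform(
      img, transform_params(p1$alpha * p2$alpha,
                            p2$alpha * p1$beta + p2$beta))
    expect_equal(two_step, one_step, tolerance = 1e-6)
  }
})

test_that("regression mapping hits the documented anchor points", {
  cfg <- regression_head_config()
  expect_equal(cfg$alpha_max, 2)
  expect_equal(cfg$beta_max, 0.1)
  p <- regression_transform_params(regression_head_output(0, 0), cfg)
  expect_equal(p$alpha, 1.0)
  expect_equal(p$beta, 0.0)
  # saturation approaches but never attains the bounds
  hi <- regression_transform_params(regression_head_output(1e6, 1e6), cfg)
  expect_lt(hi$alpha, 2)
  expect_gt(hi$alpha, 2 - 1e-6)
  expect_lt(hi$beta, 0.1)
  expect_gt(hi$beta, 0.1 - 1e-6)
  lo <- regression_transform_params(regression_head_output(-1e6, -1e6), cfg)
  expect_gt(lo$alpha, 0)
  expect_gt(lo$beta, -0.1)
  expect_lt(lo$beta, -0.1 + 1e-6)
})

test_that("regression outputs stay strictly inside their ranges on a dense sweep", {
  cfg <- regression_head_config()
  grid <- c(-10^(6:0), 0, 10^(0:6))
  grid <- sort(c(grid, seq(-20, 20, by = 0.5)))
  for (z in grid) {
    p <- regression_transform_params(regression_head_output(z, z), cfg)
    expect_gt(p$alpha, 0)
    expect_lt(p$alpha, cfg$alpha_max)
    expect_lt(abs(p$beta), cfg$beta_max)
  }
})

test_that("formulation mismatch is rejected", {
  cls <- classification_head_output(rep(0.05, 20), rep(0.2, 5))
  expect_error(regression_transform_params(cls),
               class = "dctdetect_formulation_error")
  reg <- regression_head_output(0, 0)
  expect_error(classification_transform_params(reg),
               class = "dctdetect_formulation_error")
})

test_that("alpha value grids follow the step construction", {
  expect_equal(build_alpha_values(0.1, 10), seq(0.1, 1.0, by = 0.1))
  v20 <- build_alpha_values(0.1, 20)
  expect_length(v20, 20)
  expect_equal(max(v20), 2.0)
  expect_equal(min(v20), 0.1)
  expect_equal(build_alpha_values(1, 1), 1)
  expect_true(all(diff(v20) > 0))
  expect_error(build_alpha_values(0, 5), class = "dctdetect_validation_error")
  expect_error(build_alpha_values(0.1, 0), class = "dctdetect_validation_error")
})

test_that("beta value grids are symmetric and contain zero", {
  expect_equal(build_beta_values(0.1, 2), c(-0.2, -0.1, 0, 0.1, 0.2))
  expect_equal(build_beta_values(0.05, 2), c(-0.1, -0.05, 0, 0.05, 0.1))
  expect_equal(build_beta_values(0.3, 0), 0)
  for (j in 0:4) {
    v <- build_beta_values(0.07, j)
    expect_length(v, 2 * j + 1)
    expect_equal(-v, rev(v))
    expect_true(0 %in% v)
  }
  expect_error(build_beta_values(0.1, -1), class = "dctdetect_validation_error")
})

test_that("classification mapping takes grid expectations", {
  cfg <- classification_head_config()
  # all mass on the top alpha level
  p_top <- classification_transform_params(
    classification_head_output(c(rep(0, 19), 1), c(0, 0, 1, 0, 0)), cfg)
  expect_equal(p_top$alpha, 2.0)
  expect_equal(p_top$beta, 0.0)
  # uniform over V_alpha = {0.1, ..., 1.0}: expectation is the level mean
  cfg10 <- classification_head_config(i_alpha = 0.1, k_max = 10)
  p_unif <- classification_transform_params(
    classification_head_output(rep(0.1, 10), c(0, 0, 1, 0, 0)), cfg10)
  expect_equal(p_unif$alpha, mean(build_alpha_values(0.1, 10)))
  expect_equal(p_unif$alpha, 0.55)
})

test_that("classification expectations match a direct-summation oracle and stay convex", {
  set.seed(31)
  cfg <- classification_head_config(i_alpha = 0.1, k_max = 20,
                                    i_beta = 0.05, j_max = 3)
  v_a <- build_alpha_values(cfg$i_alpha, cfg$k_max)
  v_b <- build_beta_values(cfg$i_beta, cfg$j_max)
  for (i in 1:200) {
    pa <- rexp(cfg$k_max); pa <- pa / sum(pa)
    pb <- rexp(2 * cfg$j_max + 1); pb <- pb / sum(pb)
    p <- classification_transform_params(classification_head_output(pa, pb), cfg)
    # independent summation oracle
    expect_equal(p$alpha, sum(v_a * pa), tolerance = 1e-12)
    expect_equal(p$beta, sum(v_b * pb), tolerance = 1e-12)
    expect_gte(p$alpha, min(v_a))
    expect_lte(p$alpha, max(v_a))
    expect_gte(p$beta, min(v_b))
    expect_lte(p$beta, max(v_b))
  }
})

test_that("classification head outputs are validated", {
  cfg <- classification_head_config()
  expect_error(classification_head_output(rep(0.1, 10), c(2, rep(0, 4))),
               class = "dctdetect_validation_error")  # sum != 1
  expect_error(classification_head_output(c(-0.5, 1.5), c(1)),
               class = "dctdetect_validation_error")  # negative mass
  ok <- classification_head_output(rep(0.1, 10), c(0, 0, 1, 0, 0))
  expect_error(classification_transform_params(ok, cfg),
               class = "dctdetect_validation_error")  # length mismatch (10 vs 20)
})
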