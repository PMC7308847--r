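test_that("the empty-zero reference is the per-pixel mean", {
  s <- tile_stack(list(matrix(7, 3, 3), matrix(7, 3, 3)))
  expect_equal(empty_zero_reference(s)$field[, , 1], matrix(7, 3, 3))
  s2 <- tile_stack(list(matrix(2, 1, 1), matrix(4, 1, 1)))
  m <- empty_zero_reference(s2)
  expect_equal(m$field[1, 1, 1], 3)
  expect_true(is.na(m$selected_rank))
  z <- tile_stack(list(matrix(0, 2, 2), matrix(0, 2, 2)))
  expect_error_class(empty_zero_reference(z), "shadecor_degenerate_field_error")
})

test_that("the empty-zero mean converges to the true field as n grows", {
  # Y = F (1 + noise): averaging n empty tiles shrinks the error ~ 1/sqrt(n)
  cfg <- small_config(height = 8, width = 8, channels = 1L,
                      photon_noise_sd = 0.02, seed = 11)
  emp50 <- make_empty_collection(cfg, n = 50)
  m50 <- empty_zero_reference(emp50$observed)
  rel50 <- abs(m50$field / emp50$truth_field$field - 1)
  expect_lt(max(rel50), 3 * 0.02 / sqrt(50))
  emp5 <- make_empty_collection(cfg, n = 5)
  m5 <- empty_zero_reference(emp5$observed)
  expect_lt(mean(rel50), mean(abs(m5$field / emp5$truth_field$field - 1)))
})

test_that("the correction score hits its defining endpoints exactly", {
  cfg <- small_config(height = 16, width = 16, n_tiles = 5, seed = 12)
  coll <- make_collection(cfg)
  expect_identical(
    correction_score(coll$truth_stack, coll$observed, coll$truth_stack), 0)
  expect_identical(
    correction_score(coll$observed, coll$observed, coll$truth_stack), 1)
})

test_that("the correction score is the plain ratio of summed absolute errors", {
  y <- tile_stack(list(matrix(10, 1, 1), matrix(10, 1, 1)))
  xt <- tile_stack(list(matrix(5, 1, 1), matrix(5, 1, 1)))
  xh <- tile_stack(list(matrix(6, 1, 1), matrix(6, 1, 1)))
  expect_equal(correction_score(xh, y, xt), 0.2)
  g <- correction_score(xh, y, xt, per_tile = TRUE)
  expect_equal(as.vector(attr(g, "per_tile_gamma")), c(0.2, 0.2))
  expect_error_class(correction_score(xh, xt, xt),
                     "shadecor_undefined_score_error")
  expect_error_class(
    correction_score(xh, y, tile_stack(list(matrix(5, 2, 1), matrix(5, 2, 1)))),
    "shadecor_dimension_error"
  )
})

test_that("the score is invariant to jointly permuting the three stacks", {
  cfg <- small_config(height = 16, width = 16, n_tiles = 6, seed = 13)
  coll <- make_collection(cfg)
  corr <- apply_correction(coll$observed, estimate_flat_field(coll$observed))
  g <- correction_score(corr, coll$observed, coll$truth_stack)
  p <- c(4, 6, 1, 3, 2, 5)
  shuffle <- function(s) with_tiles(s, s$tiles[, , , p, drop = FALSE])
  gp <- correction_score(shuffle(corr), shuffle(coll$observed),
                         shuffle(coll$truth_stack))
  expect_equal(gp, g, tolerance = 1e-14)
})

test_that("PSNR follows its closed forms and symmetry", {
  mk <- function(v) tile_stack(list(matrix(v, 2, 2), matrix(v, 2, 2)))
  expect_identical(psnr(mk(10), mk(10)), Inf)
  expect_equal(psnr(mk(0), mk(255), max_value = 255), 0)
  expect_equal(psnr(mk(0), mk(25.5), max_value = 255), 20)
  set.seed(14)
  a <- tile_stack(array(runif(32, 0, 255), dim = c(4, 4, 1, 2)))
  b <- tile_stack(array(runif(32, 0, 255), dim = c(4, 4, 1, 2)))
  expect_equal(psnr(a, b), psnr(b, a))
  # strictly decreasing in uniform error magnitude
  expect_gt(psnr(mk(0), mk(10)), psnr(mk(0), mk(20)))
  expect_error_class(psnr(a, mk(1)), "shadecor_dimension_error")
})

test_that("score_convergence is reproducible and degenerate at m = n", {
  cfg <- small_config(height = 32, width = 32, n_tiles = 10, seed = 15)
  coll <- make_collection(cfg)
  conv1 <- score_convergence(coll$observed, coll$truth_stack,
                             subset_sizes = c(3, 10), repeats = 3, seed = 99)
  conv2 <- score_convergence(coll$observed, coll$truth_stack,
                             subset_sizes = c(3, 10), repeats = 3, seed = 99)
  expect_identical(conv1, conv2)
  expect_equal(conv1$sd_gamma[conv1$m == 10], 0)
  expect_error_class(
    score_convergence(coll$observed, coll$truth_stack, subset_sizes = 1),
    "shadecor_insufficient_stack_error"
  )
  expect_error_class(
    score_convergence(coll$observed, coll$truth_stack, subset_sizes = 11),
    "shadecor_parameter_error"
  )
})

test_that("rank selection beats the naive mean-of-stack flat field on tiles with objects", {
  cfg <- small_config(seed = 16)
  coll <- make_collection(cfg)
  m <- estimate_flat_field(coll$observed)
  g <- correction_score(apply_correction(coll$observed, m),
                        coll$observed, coll$truth_stack)
  # mean-of-stack baseline: object pixels bias the mean downward
  mean_field <- empty_zero_reference(coll$observed)
  g_mean <- correction_score(apply_correction(coll$observed, mean_field),
                             coll$observed, coll$truth_stack)
  expect_lt(g, 1)
  expect_lt(g, g_mean)
})

test_that("empty-slide ground truth matches the preserve_mean scale", {
  # with no objects the observed stack divided by the empty-zero field is
  # flat at the field's channel mean, up to acquisition noise
  cfg <- small_config(height = 16, width = 16, n_tiles = 5,
                      object_density = 0, artifact_rate = 0, seed = 17)
  coll <- make_collection(cfg)
  emp <- make_empty_collection(cfg, n = 50)
  truth <- ground_truth_from_empty(coll$observed,
                                   empty_zero_reference(emp$observed))
  for (c in 1:3) {
    ch_mean <- mean(emp$truth_field$field[, , c])
    expect_equal(mean(truth$tiles[, , c, ]), ch_mean, tolerance = 0.02)
  }
})
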