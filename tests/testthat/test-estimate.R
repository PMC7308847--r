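test_that("candidates sort per pixel and per channel independently", {
  # single pixel, single channel: descending sort
  s <- tile_stack(list(matrix(5, 1, 1), matrix(9, 1, 1), matrix(7, 1, 1)))
  expect_equal(as.vector(build_candidates(s)$ranks[1, 1, 1, ]), c(9, 7, 5))

  # per-pixel independence: rank images need not match any input tile
  s2 <- tile_stack(list(matrix(c(1, 4), 1, 2), matrix(c(3, 2), 1, 2)))
  cand <- build_candidates(s2)
  expect_equal(cand$ranks[1, , 1, 1], c(3, 4))
  expect_equal(cand$ranks[1, , 1, 2], c(1, 2))

  # per-channel independence on a one-pixel RGB stack
  px <- function(r, g, b) array(c(r, g, b), dim = c(1, 1, 3))
  s3 <- tile_stack(list(px(10, 0, 5), px(2, 8, 5)))
  cand3 <- build_candidates(s3)
  expect_equal(as.vector(cand3$ranks[1, 1, , 1]), c(10, 8, 5))
  expect_equal(as.vector(cand3$ranks[1, 1, , 2]), c(2, 0, 5))
})

test_that("candidates match the brute-force per-pixel sort oracle exactly", {
  for (seed in 1:6) {
    set.seed(seed)
    H <- sample(2:8, 1); W <- sample(2:8, 1)
    C <- sample(c(1L, 3L), 1); n <- sample(2:5, 1)
    s <- random_stack(H, W, C, n, seed = seed + 100)
    expect_identical(build_candidates(s)$ranks, naive_candidates(s))
  }
})

test_that("candidate ranks are monotone and value-conserving per pixel", {
  s <- random_stack(6, 7, 3, 5, seed = 12)
  cand <- build_candidates(s)
  for (c in 1:3) {
    m <- matrix(cand$ranks[, , c, ], ncol = s$n)
    expect_true(all(m[, -s$n] - m[, -1] >= 0))  # non-increasing in rank
    # multiset conservation: sorted rank values equal sorted tile values
    orig <- apply(matrix(s$tiles[, , c, ], ncol = s$n), 1, sort)
    expect_equal(t(m[, s$n:1]), orig)
  }
})

test_that("local CoV matches the double-loop window oracle", {
  # windowed statistics on i.i.d. values, centers and borders alike
  for (case in list(list(H = 5, W = 5, w = 5), list(H = 8, W = 6, w = 3),
                    list(H = 7, W = 7, w = 5))) {
    set.seed(case$H * 10 + case$w)
    img <- matrix(runif(case$H * case$W, 1, 255), case$H, case$W)
    got <- local_cov(img, window = case$w, epsilon = 0)
    st <- naive_window_stats(img, case$w)
    expect_equal(got, st$sd / st$mean, tolerance = 1e-9)
    expect_equal(smoothness_score(img, case$w, 1e-3),
                 naive_smoothness(img, case$w, 1e-3), tolerance = 1e-9)
  }
  # center pixel of a 5x5 image with window 5 sees the whole image
  set.seed(1)
  img <- matrix(runif(25, 10, 200), 5, 5)
  mu <- mean(img)
  sig <- sqrt(mean((img - mu)^2))
  expect_equal(local_cov(img, 5, 0)[3, 3], sig / mu, tolerance = 1e-12)
})

test_that("smoothness is zero for constants, scale-invariant, artifact-sensitive", {
  expect_equal(smoothness_score(matrix(7, 10, 10), window = 5), 0)
  set.seed(2)
  img <- matrix(runif(100, 50, 200), 10, 10)
  expect_equal(smoothness_score(3.7 * img, 5, 0), smoothness_score(img, 5, 0),
               tolerance = 1e-12)
  # a single bright speck strictly increases the score
  spiked <- img
  spiked[5, 5] <- 255
  expect_gt(smoothness_score(spiked, 5, 0), smoothness_score(img, 5, 0))
})

test_that("window validation rejects even, nonpositive and oversized windows", {
  img <- matrix(1, 8, 8)
  expect_error_class(local_cov(img, window = 4), "shadecor_parameter_error")
  expect_error_class(local_cov(img, window = 0), "shadecor_parameter_error")
  expect_error_class(local_cov(img, window = -3), "shadecor_parameter_error")
  expect_error_class(local_cov(img, window = 17), "shadecor_parameter_error")
  expect_error_class(local_cov(img, window = 5, epsilon = -1),
                     "shadecor_parameter_error")
})

test_that("selection breaks ties toward the brighter rank and honors search_ranks", {
  # identical smooth tiles: every candidate equal, tie-break picks rank 1
  set.seed(4)
  vig <- outer(seq(180, 220, length.out = 8), seq(0.8, 1, length.out = 8))
  s <- tile_stack(replicate(4, vig, simplify = FALSE))
  m <- select_flat_field(build_candidates(s), window = 3)
  expect_equal(m$selected_rank, 1L)
  expect_equal(m$field[, , 1], vig)

  # forced selection
  m3 <- select_flat_field(build_candidates(s), window = 3, search_ranks = 3)
  expect_equal(m3$selected_rank, 3L)
  expect_true(all(is.na(m3$smoothness$scores[c(1, 2, 4), 1])))

  expect_error_class(select_flat_field(build_candidates(s), search_ranks = 9),
                     "shadecor_parameter_error")
  # zero-everywhere channel cannot produce a divisor
  z <- tile_stack(list(matrix(0, 8, 8), matrix(0, 8, 8)))
  expect_error_class(select_flat_field(build_candidates(z), window = 3),
                     "shadecor_degenerate_field_error")
})

test_that("estimation is invariant to tile order and equivariant to exposure", {
  s <- random_stack(8, 8, 3, 5, seed = 21)
  m <- estimate_flat_field(s, window = 3, epsilon = 0)
  perm <- with_tiles(s, s$tiles[, , , c(4, 1, 5, 3, 2), drop = FALSE])
  mp <- estimate_flat_field(perm, window = 3, epsilon = 0)
  expect_identical(mp$field, m$field)
  expect_identical(mp$selected_rank, m$selected_rank)
  expect_identical(mp$smoothness$scores, m$smoothness$scores)

  sc <- with_tiles(s, 0.5 * s$tiles)
  ms <- estimate_flat_field(sc, window = 3, epsilon = 0)
  expect_equal(ms$field, 0.5 * m$field, tolerance = 1e-12)
  expect_identical(ms$selected_rank, m$selected_rank)
})

test_that("a stack of identical images is its own flat field", {
  set.seed(8)
  img <- array(runif(8 * 8 * 3, 100, 200), dim = c(8, 8, 3))
  s <- tile_stack(replicate(3, img, simplify = FALSE))
  m <- estimate_flat_field(s, window = 3)
  expect_equal(m$field, img)
})

test_that("an n = 2 stack estimates without error", {
  s <- random_stack(8, 8, 1, 2, seed = 31)
  m <- estimate_flat_field(s, window = 3)
  expect_true(m$selected_rank %in% c(1L, 2L))
})

test_that("selection skips ranks contaminated by a bright artifact", {
  # smooth field, background tiles, one tile with a bright blob: the blob
  # surfaces at rank 1, so a later rank must win and equal the field
  f <- 150 + outer(sin(seq(0, 1, length.out = 32)), cos(seq(0, 1, length.out = 32))) * 30
  tiles <- replicate(6, f, simplify = FALSE)
  blob <- f
  blob[10:14, 10:14] <- 250
  tiles[[3]] <- blob
  m <- estimate_flat_field(tile_stack(tiles), window = 5, epsilon = 0)
  expect_gt(m$selected_rank, 1L)
  expect_equal(m$field[, , 1], f)
})

test_that("the estimate reproduces vignette times fixed-pattern gain", {
  # noise-free: wherever enough tiles are background, the selected rank is
  # exactly the true field, fixed-pattern noise included
  cfg <- small_config(photon_noise_sd = 0, seed = 77)
  coll <- make_collection(cfg)
  m <- estimate_flat_field(coll$observed)
  r <- stats::cor(as.vector(m$field), as.vector(coll$truth_field$field))
  expect_gt(r, 0.99)
})

test_that("dark-frame subtraction shifts the estimate accordingly", {
  set.seed(55)
  base <- array(runif(8 * 8 * 1, 100, 200), dim = c(8, 8, 1))
  s <- tile_stack(list(base[, , 1] + 10, base[, , 1] + 12))
  m <- estimate_flat_field(s, window = 3, dark_frame = matrix(10, 8, 8))
  expect_equal(max(m$field[, , 1] - base[, , 1]), 2, tolerance = 1e-12)
})
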