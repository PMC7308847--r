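# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the implementation: candidates by explicit
# per-pixel loops, window statistics by gathering each window with an index
# map.

# per-pixel descending sort, one pixel at a time
naive_candidates <- function(stack) {
  d <- dim(stack$tiles)
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (c in seq_len(d[3])) {
        out[i, j, c, ] <- sort(stack$tiles[i, j, c, ], decreasing = TRUE)
      }
    }
  }
  out
}

# symmetric (edge-repeating) reflection of an out-of-range coordinate
reflect_index <- function(idx, n) {
  ifelse(idx < 1L, 1L - idx, ifelse(idx > n, 2L * n + 1L - idx, idx))
}

# population mean/sd over the window at every pixel, by explicit gathering
naive_window_stats <- function(image, window) {
  H <- nrow(image); W <- ncol(image)
  p <- (window - 1L) %/% 2L
  mu <- matrix(0, H, W); sd_ <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ri <- reflect_index((i - p):(i + p), H)
      cj <- reflect_index((j - p):(j + p), W)
      vals <- as.vector(image[ri, cj])
      mu[i, j] <- mean(vals)
      sd_[i, j] <- sqrt(mean((vals - mu[i, j])^2))
    }
  }
  list(mean = mu, sd = sd_)
}

naive_smoothness <- function(image, window, epsilon) {
  st <- naive_window_stats(image, window)
  sum(st$sd / (st$mean + epsilon))
}

# random small stack on the 8-bit scale
random_stack <- function(H, W, C, n, seed) {
  set.seed(seed)
  tile_stack(array(runif(H * W * C * n, 0, 255), dim = c(H, W, C, n)))
}

# small synthetic config scaled down from the 256x256 defaults; object
# density is rescaled with the pixel count so coverage stays ~20%
small_config <- function(height = 64L, width = 64L, n_tiles = 30L, ...) {
  args <- list(...)
  if (is.null(args$object_density)) {
    args$object_density <- 28 * (height * width) / (256 * 256)
  }
  do.call(synth_config, c(list(height = height, width = width, n_tiles = n_tiles),
                          args))
}

expect_error_class <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
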