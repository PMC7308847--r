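#' Local coefficient of variation
#'
#' For every pixel `k`, the ratio `sigma(k) / (mu(k) + epsilon)` of the local
#' standard deviation to the local mean, both computed over a square sliding
#' window centered at `k`. The LCoV is near zero in homogeneous regions and
#' large in high-frequency regions, which makes its image-wide sum a measure
#' of how much artifact and noise structure a flat-field candidate carries.
#'
#' The standard deviation is the population form (divide by the window
#' area). Image borders are handled by symmetric reflection (the edge pixel
#' is repeated), so the statistic is defined at all `H x W` pixels.
#'
#' @param image numeric `H x W` matrix of a single channel.
#' @param window odd window side length in pixels (default 5).
#' @param epsilon nonnegative guard added to the local mean in the
#'   denominator; 0 gives the exact scale-invariant CoV.
#' @return Numeric `H x W` matrix of nonnegative LCoV values.
#' @export
#' @examples
#' local_cov(matrix(7, 8, 8), window = 5)[1, 1]  # 0: constant image
local_cov <- function(image, window = 5L, epsilon = 0) {
  check_window(window, dim(image))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0) {
    abort_parameter("`epsilon` must be a single nonnegative number")
  }
  st <- window_stats(image, window)
  st$sd / (st$mean + epsilon)
}

#' Smoothness score of a flat-field candidate channel
#'
#' The sum of the local coefficient of variation over all pixels of one
#' candidate channel. Lower is smoother; the candidate minimizing this score
#' is selected as the flat-field estimate for that channel. With
#' `epsilon = 0` the score is invariant to rescaling the image by any
#' positive constant.
#'
#' @inheritParams local_cov
#' @param candidate_channel numeric `H x W` matrix (one channel of a rank
#'   image).
#' @return A single nonnegative number.
#' @export
smoothness_score <- function(candidate_channel, window = 5L, epsilon = 0) {
  sum(local_cov(candidate_channel, window = window, epsilon = epsilon))
}

check_window <- function(window, dims = NULL) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window != as.integer(window) || as.integer(window) %% 2L == 0L) {
    abort_parameter(sprintf(
      "`window` must be a positive odd integer, got %s", format(window)
    ))
  }
  if (!is.null(dims)) {
    p <- (as.integer(window) - 1L) %/% 2L
    if (p >= min(dims[1:2])) {
      abort_parameter(sprintf(
        "window %d is too large for a %d x %d image", window, dims[1], dims[2]
      ))
    }
  }
  invisible(as.integer(window))
}

# windowed population mean and sd with symmetric (edge-repeating) padding,
# computed by shift-and-add of the padded image (exact summation, no
# cumulative-sum cancellation)
window_stats <- function(image, window) {
  H <- nrow(image); W <- ncol(image)
  p <- (as.integer(window) - 1L) %/% 2L
  if (p == 0L) {
    return(list(mean = image, sd = matrix(0, H, W)))
  }
  P <- image[c(p:1, seq_len(H), H:(H - p + 1L)), , drop = FALSE]
  P <- P[, c(p:1, seq_len(W), W:(W - p + 1L)), drop = FALSE]
  s <- matrix(0, H, W)
  s2 <- matrix(0, H, W)
  for (dx in 0:(2L * p)) {
    rows <- (1L + dx):(H + dx)
    for (dy in 0:(2L * p)) {
      blk <- P[rows, (1L + dy):(W + dy), drop = FALSE]
      s <- s + blk
      s2 <- s2 + blk * blk
    }
  }
  area <- (2 * p + 1)^2
  mu <- s / area
  list(mean = mu, sd = sqrt(pmax(s2 / area - mu * mu, 0)))
}
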