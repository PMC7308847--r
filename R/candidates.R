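#' Build flat-field candidates by per-pixel rank sorting
#'
#' At every pixel and in every channel independently, the intensities of the
#' `n` tiles are sorted in descending order. Rank image `r` then holds, at
#' each pixel, the `r`-th largest intensity observed across the stack: rank 1
#' is the per-pixel maximum (the brightest candidate), rank `n` the per-pixel
#' minimum. Under brightfield illumination background pixels are brighter
#' than object pixels, so low ranks approximate the flat field wherever the
#' background was observed often enough — but tiles with bright artifacts
#' (dust, bubbles) contaminate the lowest ranks, which is why a smoothness
#' criterion chooses among the ranks afterwards.
#'
#' Channels are sorted independently, so a given rank image need not
#' correspond to any single input tile.
#'
#' @param stack a [tile_stack()] with `n >= 2`.
#' @return An object of class `flat_field_candidates`: a list with `ranks`
#'   (numeric `H x W x C x n` array, 4th dimension indexed by rank),
#'   `n` and `bit_depth_max`.
#' @export
#' @examples
#' s <- tile_stack(list(matrix(5, 1, 1), matrix(9, 1, 1), matrix(7, 1, 1)))
#' build_candidates(s)$ranks[1, 1, 1, ]  # 9 7 5
build_candidates <- function(stack) {
  stopifnot(inherits(stack, "tile_stack"))
  if (stack$n < 2L) {
    abort_insufficient_stack("candidate construction needs at least 2 tiles")
  }
  d <- dim(stack$tiles)
  H <- d[1]; W <- d[2]; C <- d[3]; n <- d[4]
  ranks <- array(0, dim = d)
  for (c in seq_len(C)) {
    M <- matrix(stack$tiles[, , c, ], nrow = H * W, ncol = n)
    # vectorized row-wise sort: order by (row, value), refill row-major
    idx <- order(row(M), M)
    sorted <- matrix(M[idx], nrow = H * W, byrow = TRUE)
    ranks[, , c, ] <- sorted[, n:1]  # descending: rank 1 = brightest
  }
  structure(
    list(ranks = ranks, n = as.integer(n), bit_depth_max = stack$bit_depth_max),
    class = "flat_field_candidates"
  )
}

#' @export
print.flat_field_candidates <- function(x, ...) {
  d <- dim(x$ranks)
  cat(sprintf("<flat_field_candidates> %d rank images of %d x %d x %d\n",
              x$n, d[1], d[2], d[3]))
  invisible(x)
}

# rank image r for channel c as an H x W matrix
candidate_channel <- function(candidates, rank, channel) {
  candidates$ranks[, , channel, rank, drop = FALSE][, , 1, 1]
}
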