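#' Select the flat-field estimate among rank candidates
#'
#' Computes the smoothness score of every searched rank image, per channel,
#' and selects for each channel the rank with the minimum score. Ties are
#' broken toward the smaller rank, i.e. the brighter candidate, which is
#' closer to the background-maximum ideal. The per-channel winners are merged
#' into one multichannel flat field. No smoothing is applied to the selected
#' field at any point: static per-pixel gain variation (fixed-pattern noise)
#' present in the tiles is deliberately retained in the estimate so that the
#' division correction removes it.
#'
#' @param candidates a [build_candidates()] result.
#' @param window odd side length of the LCoV sliding window (default 5).
#' @param epsilon denominator guard for the LCoV; `NULL` (default) uses
#'   `1e-6 * bit_depth_max`.
#' @param search_ranks integer subset of `1..n` to score; default all ranks.
#' @return An object of class `flat_field_model`: list with
#'   `field` (`H x W x C`), `selected_rank` (length-`C` integer),
#'   `smoothness` (class `smoothness_profile`: `scores` is an `n x C` matrix
#'   with `NA` at unsearched ranks, plus `window` and `epsilon`),
#'   `dark_field` (all zeros), and `bit_depth_max`.
#' @export
select_flat_field <- function(candidates, window = 5L, epsilon = NULL,
                              search_ranks = NULL) {
  stopifnot(inherits(candidates, "flat_field_candidates"))
  n <- candidates$n
  d <- dim(candidates$ranks)
  check_window(window, d)
  if (is.null(epsilon)) epsilon <- 1e-6 * candidates$bit_depth_max
  if (is.null(search_ranks)) search_ranks <- seq_len(n)
  search_ranks <- sort(unique(as.integer(search_ranks)))
  if (length(search_ranks) == 0L || min(search_ranks) < 1L || max(search_ranks) > n) {
    abort_parameter(sprintf("`search_ranks` must be a nonempty subset of 1..%d", n))
  }
  C <- d[3]
  scores <- matrix(NA_real_, nrow = n, ncol = C)
  selected <- integer(C)
  field <- array(0, dim = d[1:3])
  for (c in seq_len(C)) {
    all_zero <- TRUE
    for (r in search_ranks) {
      ch <- candidate_channel(candidates, r, c)
      if (any(ch > 0)) all_zero <- FALSE
      scores[r, c] <- smoothness_score(ch, window = window, epsilon = epsilon)
    }
    if (all_zero) {
      abort_degenerate_field(sprintf(
        "channel %d is zero in every searched candidate; cannot form a divisor field", c
      ))
    }
    # global minimum; which.min returns the first (smallest, brightest rank) on ties
    best <- search_ranks[which.min(scores[search_ranks, c])]
    selected[c] <- best
    field[, , c] <- candidate_channel(candidates, best, c)
  }
  profile <- structure(
    list(scores = scores, window = as.integer(window), epsilon = epsilon),
    class = "smoothness_profile"
  )
  new_flat_field_model(field, selected, profile, candidates$bit_depth_max)
}

new_flat_field_model <- function(field, selected_rank, smoothness, bit_depth_max) {
  structure(
    list(
      field = field,
      selected_rank = selected_rank,
      smoothness = smoothness,
      dark_field = array(0, dim = dim(field)),
      bit_depth_max = bit_depth_max
    ),
    class = "flat_field_model"
  )
}

#' @export
print.flat_field_model <- function(x, ...) {
  d <- dim(x$field)
  rk <- if (all(is.na(x$selected_rank))) "(none: reference field)"
        else paste(x$selected_rank, collapse = ", ")
  cat(sprintf("<flat_field_model> %d x %d x %d, selected rank(s): %s, range [%g, %g]\n",
              d[1], d[2], d[3], rk, min(x$field), max(x$field)))
  invisible(x)
}

#' @export
print.smoothness_profile <- function(x, ...) {
  cat(sprintf("<smoothness_profile> %d ranks x %d channel(s), window %d, epsilon %g\n",
              nrow(x$scores), ncol(x$scores), x$window, x$epsilon))
  invisible(x)
}

#' Estimate the flat-field distortion of a tile stack
#'
#' One-call entry point for the two-step estimator: build per-pixel rank
#' candidates with [build_candidates()], then pick the smoothest rank per
#' channel with [select_flat_field()]. The result is the multiplicative
#' flat field `F` of the image-formation model `Y_i(k) = X_i(k) * F(k)`
#' (dark field assumed zero), used by [apply_correction()] to recover the
#' tiles' content by division.
#'
#' @param stack a [tile_stack()] of `n >= 2` tiles from one slide.
#' @inheritParams select_flat_field
#' @param dark_frame optional `H x W x C` (or `H x W`) dark-field frame
#'   subtracted from every tile (clamped at 0) before estimation; off by
#'   default since the dark field is assumed zero.
#' @return A `flat_field_model` (see [select_flat_field()]).
#' @export
#' @examples
#' set.seed(1)
#' tiles <- replicate(4, matrix(200 + rnorm(64, sd = 2), 8, 8), simplify = FALSE)
#' m <- estimate_flat_field(tile_stack(tiles), window = 3)
#' m$selected_rank
estimate_flat_field <- function(stack, window = 5L, epsilon = NULL,
                                search_ranks = NULL, dark_frame = NULL) {
  stopifnot(inherits(stack, "tile_stack"))
  if (!is.null(dark_frame)) {
    dk <- as_hwc(dark_frame)
    if (!identical(dim(dk), dim(stack$tiles)[1:3])) {
      abort_dimension("dark frame dimensions do not match the tiles")
    }
    tiles <- pmax(stack$tiles - as.vector(dk), 0)
    stack <- with_tiles(stack, array(tiles, dim = dim(stack$tiles)))
  }
  candidates <- build_candidates(stack)
  select_flat_field(candidates, window = window, epsilon = epsilon,
                    search_ranks = search_ranks)
}

#' Write / read a flat-field model as 32-bit float TIFF plus JSON sidecar
#'
#' The field is stored normalized by `bit_depth_max` in a float TIFF; the
#' sidecar `<path>.json` records `bit_depth_max`, the selected ranks, window
#' and epsilon so the model round-trips.
#'
#' @param model a `flat_field_model`.
#' @param path output `.tif` path.
#' @return `write_model()`: invisibly, `path`. `read_model()`: the model.
#' @export
write_model <- function(model, path) {
  img <- drop_singleton_channel(model$field / model$bit_depth_max)
  suppressWarnings(tiff::writeTIFF(img, path, bits.per.sample = 32L))
  sidecar <- list(
    bit_depth_max = model$bit_depth_max,
    selected_rank = model$selected_rank,
    window = if (!is.null(model$smoothness)) model$smoothness$window else NULL,
    epsilon = if (!is.null(model$smoothness)) model$smoothness$epsilon else NULL
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  img <- as_hwc(tiff::readTIFF(path))
  sidecar_path <- paste0(path, ".json")
  depth <- 255
  rank <- rep(NA_integer_, dim(img)[3])
  smoothness <- NULL
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sc$bit_depth_max)) depth <- sc$bit_depth_max
    if (!is.null(sc$selected_rank)) rank <- as.integer(sc$selected_rank)
  }
  new_flat_field_model(img * depth, rank, smoothness, depth)
}

#' Smoothness profile as a data frame
#'
#' Long-format table of the per-rank, per-channel smoothness scores computed
#' during selection, suitable for plotting or CSV export (rank vs. S curve).
#'
#' @param model a `flat_field_model` from [estimate_flat_field()].
#' @return A data frame with columns `rank`, `channel`, `score` (searched
#'   ranks only).
#' @export
smoothness_table <- function(model) {
  sc <- model$smoothness$scores
  C <- ncol(sc)
  ch_names <- if (C == 3L) c("red", "green", "blue") else paste0("ch", seq_len(C))
  out <- data.frame(
    rank = rep(seq_len(nrow(sc)), times = C),
    channel = rep(ch_names, each = nrow(sc)),
    score = as.vector(sc)
  )
  out[!is.na(out$score), , drop = FALSE]
}
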