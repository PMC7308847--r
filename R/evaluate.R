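#' Empty-zero reference flat field
#'
#' Prospective reference estimator: the flat field is the per-pixel,
#' per-channel arithmetic mean of images of an empty slide acquired at
#' various stage positions. With no sample on the slide the observed image
#' is the flat field itself plus acquisition noise, so averaging converges
#' to the field. Used here to construct ground truth for evaluating the
#' retrospective estimator.
#'
#' @param empty_stack a [tile_stack()] of `n >= 1` empty-slide tiles
#'   (build with `allow_single = TRUE` for a single reference image).
#' @return A `flat_field_model` whose `field` is the per-pixel mean;
#'   `selected_rank` is `NA` (no rank selection is involved) and the
#'   smoothness profile is absent.
#' @export
#' @examples
#' s <- tile_stack(list(matrix(2, 2, 2), matrix(4, 2, 2)))
#' empty_zero_reference(s)$field[1, 1, 1]  # 3
empty_zero_reference <- function(empty_stack) {
  stopifnot(inherits(empty_stack, "tile_stack"))
  d <- dim(empty_stack$tiles)
  field <- array(rowMeans(matrix(empty_stack$tiles, nrow = prod(d[1:3]), ncol = d[4])),
                 dim = d[1:3])
  if (min(field) <= 0) {
    abort_degenerate_field("empty-slide mean is zero at some pixel; cannot serve as a divisor field")
  }
  new_flat_field_model(field, rep(NA_integer_, d[3]), NULL,
                       empty_stack$bit_depth_max)
}

#' Correction score
#'
#' Ratio of the summed absolute error of the corrected stack to that of the
#' uncorrected stack, both against ground truth:
#' `Gamma = sum_i |Xhat_i - Xtrue_i| / sum_i |Y_i - Xtrue_i|`,
#' with the sums running over all pixels, channels and tiles. 0 indicates
#' perfect correction, 1 the same amount of error as the uncorrected input,
#' and values above 1 a correction that made things worse.
#'
#' The ratio is computed exactly as defined, with no internal rescaling: the
#' caller is responsible for supplying `corrected` and `ground_truth` on a
#' common intensity scale (see [ground_truth_from_empty()] for the
#' empty-slide convention used by the evaluation pipeline).
#'
#' @param corrected,uncorrected,ground_truth three [tile_stack()]s of
#'   identical shape and tile count.
#' @param per_tile also return the per-tile ratios as attribute
#'   `"per_tile_gamma"` (diagnostic only; the score itself is the single
#'   collection-wide ratio).
#' @return A single nonnegative number.
#' @export
#' @examples
#' y <- tile_stack(list(matrix(10, 1, 1), matrix(10, 1, 1)))
#' xt <- tile_stack(list(matrix(5, 1, 1), matrix(5, 1, 1)))
#' xh <- tile_stack(list(matrix(6, 1, 1), matrix(6, 1, 1)))
#' correction_score(xh, y, xt)  # 0.2
correction_score <- function(corrected, uncorrected, ground_truth,
                             per_tile = FALSE) {
  stopifnot(inherits(corrected, "tile_stack"), inherits(uncorrected, "tile_stack"),
            inherits(ground_truth, "tile_stack"))
  d <- dim(corrected$tiles)
  if (!identical(d, dim(uncorrected$tiles)) || !identical(d, dim(ground_truth$tiles))) {
    abort_dimension("corrected, uncorrected and ground-truth stacks must have identical shape")
  }
  num <- abs(corrected$tiles - ground_truth$tiles)
  den <- abs(uncorrected$tiles - ground_truth$tiles)
  den_total <- sum(den)
  if (den_total == 0) {
    abort_undefined_score("uncorrected stack already equals ground truth; the score is undefined")
  }
  gamma <- sum(num) / den_total
  if (per_tile) {
    num_t <- apply(num, 4L, sum)
    den_t <- apply(den, 4L, sum)
    attr(gamma, "per_tile_gamma") <- ifelse(den_t > 0, num_t / den_t, NA_real_)
  }
  gamma
}

#' Ground truth via the empty-zero convention
#'
#' Divides each observed tile by the empty-zero reference field and rescales
#' per channel by that field's spatial mean, producing a ground-truth stack
#' on the same intensity scale as a `preserve_mean` correction, so that the
#' two can be compared by [correction_score()] and [psnr()].
#'
#' @param stack the observed (uncorrected) [tile_stack()].
#' @param empty_model an [empty_zero_reference()] model.
#' @return A [tile_stack()] of ground-truth tiles.
#' @export
ground_truth_from_empty <- function(stack, empty_model) {
  apply_correction(stack, empty_model, scale_mode = "preserve_mean")
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_value^2 / MSE)` in decibels, with the mean squared error
#' averaged over all pixels, channels and tiles. Returns `Inf` when the
#' stacks are identical. Higher is better.
#'
#' @param corrected,ground_truth two [tile_stack()]s of identical shape.
#' @param max_value peak intensity; defaults to the stack's
#'   `bit_depth_max` (the standard convention), not the observed maximum.
#' @return PSNR in dB (possibly `Inf`).
#' @export
#' @examples
#' a <- tile_stack(list(matrix(0, 2, 2), matrix(0, 2, 2)))
#' b <- tile_stack(list(matrix(25.5, 2, 2), matrix(25.5, 2, 2)))
#' psnr(a, b, max_value = 255)  # 20 dB: uniform error of max/10
psnr <- function(corrected, ground_truth, max_value = NULL) {
  stopifnot(inherits(corrected, "tile_stack"), inherits(ground_truth, "tile_stack"))
  if (!identical(dim(corrected$tiles), dim(ground_truth$tiles))) {
    abort_dimension("stacks must have identical shape for PSNR")
  }
  if (is.null(max_value)) max_value <- corrected$bit_depth_max
  if (!is.numeric(max_value) || max_value <= 0) {
    abort_parameter("`max_value` must be positive")
  }
  mse <- mean((corrected$tiles - ground_truth$tiles)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Correction score as a function of the number of images
#'
#' Measures how many tiles are needed to model the shading distortion: for
#' each subset size `m`, draws `repeats` random `m`-subsets of the stack,
#' estimates the flat field on each subset alone, corrects the full stack
#' with it, and computes the correction score against ground truth. Reports
#' the mean and standard deviation over the repeats.
#'
#' Subset draws are reproducible: each `(m, repeat)` cell uses its own
#' substream seeded as `seed + 1000 * m + repeat` (kept independent of
#' evaluation order).
#'
#' @param stack the full observed [tile_stack()].
#' @param ground_truth ground-truth [tile_stack()] on the same scale as a
#'   `preserve_mean` correction.
#' @param subset_sizes integer vector of subset sizes `m` (each `>= 2`,
#'   `<= n`).
#' @param repeats random subsets per size (default 5).
#' @param seed integer base seed.
#' @inheritParams estimate_flat_field
#' @param scale_mode passed to [apply_correction()].
#' @return A data frame with columns `m`, `mean_gamma`, `sd_gamma`.
#' @export
score_convergence <- function(stack, ground_truth, subset_sizes, repeats = 5L,
                              seed = 1L, window = 5L, epsilon = NULL,
                              scale_mode = "preserve_mean") {
  stopifnot(inherits(stack, "tile_stack"))
  subset_sizes <- as.integer(subset_sizes)
  if (any(subset_sizes < 2L)) {
    abort_insufficient_stack("subset sizes below 2 cannot support estimation")
  }
  if (any(subset_sizes > stack$n)) {
    abort_parameter(sprintf("subset sizes must not exceed n = %d", stack$n))
  }
  if (repeats < 1L) abort_parameter("`repeats` must be >= 1")
  d <- dim(stack$tiles)
  res <- lapply(subset_sizes, function(m) {
    gammas <- vapply(seq_len(repeats), function(rep_i) {
      sub_seed <- (as.integer(seed) + 1000L * m + rep_i) %% .Machine$integer.max
      idx <- withr_seed(sub_seed, sample.int(stack$n, m))
      sub <- with_tiles(stack, stack$tiles[, , , idx, drop = FALSE])
      model <- estimate_flat_field(sub, window = window, epsilon = epsilon)
      corrected <- apply_correction(stack, model, scale_mode = scale_mode)
      correction_score(corrected, stack, ground_truth)
    }, numeric(1))
    data.frame(m = m, mean_gamma = mean(gammas), sd_gamma = stats::sd(gammas))
  })
  do.call(rbind, res)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
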