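#' Apply shading correction to a tile stack
#'
#' Reverses the image-formation model `Y_i(k) = X_i(k) * F(k)` by per-pixel
#' division: `X_hat_i(k) = (Y_i(k) - D(k)) / F_hat(k)` in every channel,
#' where `D` is the (normally all-zero) dark field stored in the model.
#' Because the estimated field retains fixed-pattern gain variation, the
#' division removes that variation from the tiles along with the smooth
#' shading.
#'
#' In `"raw"` mode the result is on the transmittance scale (background near
#' 1). The default `"preserve_mean"` mode rescales each channel by the
#' spatial mean of the field, restoring the original intensity scale, which
#' is the convention used for display and evaluation. Returned values are
#' never clipped; clipping to `[0, bit_depth_max]` happens only when integer
#' files are written.
#'
#' @param stack a [tile_stack()] of observed tiles.
#' @param model a `flat_field_model` whose field matches the tile shape and
#'   is strictly positive.
#' @param scale_mode `"preserve_mean"` (default) or `"raw"`.
#' @return A [tile_stack()] of corrected tiles (same metadata as `stack`).
#' @export
#' @examples
#' f <- array(c(100, 200, 150, 250), dim = c(2, 2, 1))
#' s <- tile_stack(list(f[, , 1], f[, , 1] / 2))
#' m <- shadecor:::new_flat_field_model(f, 1L, NULL, 255)
#' get_tile(apply_correction(s, m, scale_mode = "raw"), 1)  # all ones
apply_correction <- function(stack, model, scale_mode = c("preserve_mean", "raw")) {
  scale_mode <- match.arg(scale_mode)
  stopifnot(inherits(stack, "tile_stack"), inherits(model, "flat_field_model"))
  d <- dim(stack$tiles)
  if (!identical(d[1:3], dim(model$field))) {
    abort_dimension(sprintf(
      "tile shape %s does not match field shape %s",
      paste(d[1:3], collapse = "x"), paste(dim(model$field), collapse = "x")
    ))
  }
  if (min(model$field) <= 0) {
    abort_degenerate_field("flat field must be strictly positive for division")
  }
  y <- stack$tiles
  if (any(model$dark_field != 0)) {
    y <- pmax(y - as.vector(model$dark_field), 0)
    y <- array(y, dim = d)
  }
  out <- y / as.vector(model$field)  # field recycles over the tile dimension
  if (scale_mode == "preserve_mean") {
    ch_means <- apply(model$field, 3L, mean)
    scale <- array(rep(ch_means, each = d[1] * d[2]), dim = d[1:3])
    out <- out * as.vector(scale)
  }
  with_tiles(stack, array(out, dim = d))
}

#' Correct an image collection on disk
#'
#' Loads a tile collection, estimates its flat field if no model is given
#' (the retrospective use case), corrects every tile, and writes the results
#' plus the model used. Output tiles keep the input dtype and naming with a
#' configurable suffix.
#'
#' @param input directory of TIFF/PNG tiles, file vector, or multi-page TIFF.
#' @param output_dir directory for corrected tiles (created if missing).
#' @param model optional `flat_field_model`; when `NULL` it is estimated
#'   from the input stack itself.
#' @inheritParams estimate_flat_field
#' @inheritParams apply_correction
#' @param suffix appended to output file names before the extension.
#' @param write_float write corrected tiles as 32-bit float TIFF (normalized
#'   by `bit_depth_max`) instead of the input integer dtype, avoiding
#'   clipping.
#' @return Invisibly, a list with the corrected `stack`, the `model` used,
#'   and the written `files`.
#' @export
correct_collection <- function(input, output_dir, model = NULL, window = 5L,
                               epsilon = NULL, search_ranks = NULL,
                               scale_mode = c("preserve_mean", "raw"),
                               suffix = "_corrected", write_float = FALSE) {
  scale_mode <- match.arg(scale_mode)
  stack <- load_stack(input)
  if (is.null(model)) {
    model <- estimate_flat_field(stack, window = window, epsilon = epsilon,
                                 search_ranks = search_ranks)
  }
  corrected <- apply_correction(stack, model, scale_mode = scale_mode)
  if (write_float) corrected$dtype <- "float"
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- write_stack(corrected, output_dir, prefix = "tile_", suffix = suffix)
  # the model lives in a subdirectory so the corrected tiles load cleanly
  model_dir <- file.path(output_dir, "model")
  if (!dir.exists(model_dir)) dir.create(model_dir)
  write_model(model, file.path(model_dir, "flatfield.tif"))
  invisible(list(stack = corrected, model = model, files = files))
}
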