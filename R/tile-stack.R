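#' Tile stacks
#'
#' A `tile_stack` holds `n` same-sized brightfield tiles acquired at different
#' stage positions of one slide, as a numeric `H x W x C x n` array (`C` is 1
#' for grayscale, 3 for RGB). Intensities are nonnegative reals on the native
#' intensity scale of the source images (0..255 for 8-bit, 0..65535 for
#' 16-bit), so that the division in the shading-correction model is exact;
#' the source sample format is kept as metadata so corrected tiles can be
#' written back in the input dtype.
#'
#' @param tiles either a numeric `H x W x C x n` array, or a list of `n`
#'   images each given as an `H x W` matrix or `H x W x C` array. All tiles
#'   must share identical dimensions.
#' @param bit_depth_max maximum representable intensity of the source format
#'   (255 for 8-bit, 65535 for 16-bit, 1 for unit-scale float data).
#' @param dtype storage type used when tiles are written: `"uint8"`,
#'   `"uint16"` or `"float"`.
#' @param allow_single permit `n = 1`. Rank-sorting a single tile is
#'   degenerate, so stacks destined for flat-field estimation require
#'   `n >= 2`; single-tile stacks are only meaningful as e.g. an empty-slide
#'   reference.
#'
#' @return An object of class `tile_stack` with elements `tiles` (the 4-d
#'   array), `n`, `bit_depth_max` and `dtype`.
#' @export
#' @examples
#' s <- tile_stack(list(matrix(100, 4, 4), matrix(150, 4, 4)))
#' s$n
#' dim(s$tiles)
tile_stack <- function(tiles, bit_depth_max = 255, dtype = c("uint8", "uint16", "float"),
                       allow_single = FALSE) {
  dtype <- match.arg(dtype)
  if (is.list(tiles)) {
    tiles <- lapply(tiles, as_hwc)
    d1 <- dim(tiles[[1]])
    for (i in seq_along(tiles)) {
      if (!identical(dim(tiles[[i]]), d1)) {
        abort_dimension(sprintf(
          "tile %d has dimensions %s; expected %s (all tiles must match)",
          i, paste(dim(tiles[[i]]), collapse = "x"), paste(d1, collapse = "x")
        ))
      }
    }
    arr <- array(unlist(tiles, use.names = FALSE), dim = c(d1, length(tiles)))
  } else if (is.array(tiles) && length(dim(tiles)) == 4L) {
    arr <- tiles
    storage.mode(arr) <- "double"
  } else {
    abort_parameter("`tiles` must be a list of images or an H x W x C x n array")
  }
  n <- dim(arr)[4]
  if (n < 2L && !allow_single) {
    abort_insufficient_stack(sprintf(
      "a tile stack needs at least 2 tiles for estimation; got %d", n
    ))
  }
  if (!dim(arr)[3] %in% c(1L, 3L)) {
    abort_dimension(sprintf("tiles must have 1 or 3 channels, not %d", dim(arr)[3]))
  }
  if (anyNA(arr) || min(arr) < 0 || max(arr) > bit_depth_max) {
    abort_parameter(sprintf(
      "tile intensities must be finite and within [0, %g]", bit_depth_max
    ))
  }
  structure(
    list(tiles = arr, n = as.integer(n), bit_depth_max = bit_depth_max, dtype = dtype),
    class = "tile_stack"
  )
}

# coerce a single image to H x W x C (C in {1,3}); drops an alpha channel
as_hwc <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort_dimension("each tile must be an H x W matrix or H x W x C array")
  }
  if (dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 2L) x <- x[, , 1L, drop = FALSE]
  storage.mode(x) <- "double"
  x
}

#' @export
print.tile_stack <- function(x, ...) {
  d <- dim(x$tiles)
  cat(sprintf(
    "<tile_stack> %d tiles of %d x %d x %d (%s, max %g), intensity range [%g, %g]\n",
    x$n, d[1], d[2], d[3], x$dtype, x$bit_depth_max, min(x$tiles), max(x$tiles)
  ))
  invisible(x)
}

#' @export
dim.tile_stack <- function(x) dim(x$tiles)

#' Extract one tile from a stack
#'
#' @param stack a [tile_stack()].
#' @param i tile index in `1..n`.
#' @return The `H x W x C` array of tile `i`.
#' @export
get_tile <- function(stack, i) {
  stack$tiles[, , , i, drop = FALSE][, , , 1]
}

#' Replace the pixel data of a stack, keeping its metadata
#'
#' @param stack a [tile_stack()] supplying `bit_depth_max` and `dtype`.
#' @param tiles a new `H x W x C x n` array (values may exceed the bit depth;
#'   they are only clipped when written as integers).
#' @return A `tile_stack` sharing `stack`'s metadata.
#' @export
with_tiles <- function(stack, tiles) {
  out <- stack
  out$tiles <- tiles
  out$n <- as.integer(dim(tiles)[4])
  out
}

#' Read a tile stack from image files
#'
#' Accepts a directory of TIFF/PNG files (read in lexicographic order), a
#' character vector of file paths, or a single multi-page TIFF. Intensities
#' are converted to doubles on the native scale of the source bit depth.
#'
#' @param paths directory, file vector, or one multi-page TIFF.
#' @param channel_mode `"auto"` keeps the channels found in the files,
#'   `"gray"` collapses RGB to luma (Rec. 709 weights), `"rgb"` replicates a
#'   gray channel to three.
#' @param allow_single permit a single image (see [tile_stack()]).
#' @return A [tile_stack()]. The source file names are attached as attribute
#'   `"sources"` when reading from files (page indices for multi-page TIFF).
#' @export
load_stack <- function(paths, channel_mode = c("auto", "gray", "rgb"),
                       allow_single = FALSE) {
  channel_mode <- match.arg(channel_mode)
  if (length(paths) == 1L && dir.exists(paths)) {
    files <- list.files(paths, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- sort(files)
    if (length(files) == 0L) {
      abort_insufficient_stack(sprintf("no TIFF/PNG files found in '%s'", paths))
    }
    paths <- files
  }
  imgs <- list()
  names_out <- character()
  depth <- NULL
  for (p in paths) {
    if (!file.exists(p)) abort_io(sprintf("cannot read '%s': no such file", p))
    rd <- read_image_file(p)
    for (j in seq_along(rd$images)) {
      imgs[[length(imgs) + 1L]] <- rd$images[[j]]
      names_out <- c(names_out,
                     if (length(rd$images) > 1L) sprintf("%s#%d", basename(p), j)
                     else basename(p))
    }
    if (is.null(depth)) depth <- rd$bit_depth_max
    else if (!isTRUE(all.equal(depth, rd$bit_depth_max))) {
      abort_io(sprintf("'%s' has a different bit depth than earlier files", p))
    }
  }
  if (length(imgs) < 2L && !allow_single) {
    abort_insufficient_stack(sprintf(
      "need at least 2 tiles, found %d", length(imgs)
    ))
  }
  imgs <- lapply(imgs, apply_channel_mode, channel_mode = channel_mode)
  d1 <- dim(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d1)) {
      abort_dimension(sprintf(
        "'%s' has dimensions %s; expected %s",
        names_out[i], paste(dim(imgs[[i]]), collapse = "x"),
        paste(d1, collapse = "x")
      ))
    }
  }
  dtype <- if (depth >= 65535) "uint16" else if (depth >= 255) "uint8" else "float"
  st <- tile_stack(imgs, bit_depth_max = depth, dtype = dtype,
                   allow_single = allow_single)
  attr(st, "sources") <- names_out
  st
}

# read one file; returns list(images = list of H x W x C, bit_depth_max)
read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    raw <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) abort_io(sprintf("cannot read '%s': %s",
                                                         path, conditionMessage(e))))
    bits <- attr(raw[[1]], "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    if (bits[1] >= 32L) {
      depth <- 1  # float samples are used as stored
      imgs <- lapply(raw, as_hwc)
    } else {
      # readTIFF normalizes integer samples to [0,1]; restore the native
      # scale exactly (int/depth * depth rounds back to the integer)
      depth <- 2^bits[1] - 1
      imgs <- lapply(raw, function(im) round(as_hwc(im) * depth))
    }
    list(images = imgs, bit_depth_max = depth)
  } else if (ext == "png") {
    img <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) abort_io(sprintf("cannot read '%s': %s",
                                                         path, conditionMessage(e))))
    info <- attr(img, "info")
    bits <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 8L
    depth <- 2^bits - 1
    # readPNG normalizes to [0,1]; restore the native integer scale
    list(images = list(as_hwc(img * depth)), bit_depth_max = depth)
  } else {
    abort_io(sprintf("unsupported image format '%s' for '%s'", ext, path))
  }
}

apply_channel_mode <- function(img, channel_mode) {
  if (channel_mode == "gray" && dim(img)[3] == 3L) {
    g <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    img <- array(g, dim = c(dim(g), 1L))
  } else if (channel_mode == "rgb" && dim(img)[3] == 1L) {
    img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  }
  img
}

#' Write a tile stack to TIFF
#'
#' Integer dtypes are clipped to `[0, bit_depth_max]` and rounded at write
#' time only; the in-memory stack is never clipped. Float stacks are written
#' as 32-bit float TIFF without clipping.
#'
#' @param stack a [tile_stack()].
#' @param path output directory (one file per tile) or a single `.tif` path
#'   (multi-page).
#' @param prefix,suffix file naming for directory output:
#'   `<prefix><index><suffix>.tif`.
#' @return Invisibly, the written file path(s).
#' @export
write_stack <- function(stack, path, prefix = "tile_", suffix = "") {
  imgs <- lapply(seq_len(stack$n), function(i) {
    encode_for_tiff(get_tile(stack, i), stack$bit_depth_max, stack$dtype)
  })
  bps <- switch(stack$dtype, uint8 = 8L, uint16 = 16L, float = 32L)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(imgs, path, bits.per.sample = bps)
    invisible(path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    fmt <- sprintf("%s%%0%dd%s.tif", prefix, nchar(as.character(stack$n)), suffix)
    files <- file.path(path, sprintf(fmt, seq_len(stack$n)))
    for (i in seq_len(stack$n)) {
      tiff::writeTIFF(imgs[[i]], files[i], bits.per.sample = bps)
    }
    invisible(files)
  }
}

# writeTIFF expects [0,1] doubles; quantize integer dtypes so the round trip
# is bit-exact. Float output is stored normalized by bit_depth_max; values
# outside [0,1] wrap in libtiff, so they are clamped.
encode_for_tiff <- function(img, depth, dtype) {
  img <- drop_singleton_channel(img)
  if (dtype == "float") return(pmin(pmax(img / depth, 0), 1))
  round(pmin(pmax(img, 0), depth)) / depth
}

drop_singleton_channel <- function(img) {
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img[, , 1] else img
}
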