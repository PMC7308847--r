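#' Configuration for synthetic brightfield tile collections
#'
#' Describes a simulated whole-slide acquisition with known ground truth.
#' The simulated flat field is a smooth radial vignette multiplied by a
#' static per-pixel gain (fixed-pattern noise); tiles are bright background
#' with darker cell-like elliptical objects, a minority of tiles carry a
#' bright bubble ring or dark dust speck, and each acquisition adds
#' multiplicative zero-mean noise. The defaults emulate a 40x brightfield
#' scan: background at 200 of 255, 30% corner vignetting, 2% fixed-pattern
#' gain sd, roughly 20% of each tile covered by objects at half
#' transmittance, 10% of tiles carrying an artifact, and 1% photon noise.
#' Object sizes are fixed in pixels (ellipse semi-axes 6-20 px), so the
#' default `object_density` of 28 is calibrated for the default 256 x 256
#' tile (expected coverage `1 - (1 - 531/65536)^28`, about 20%); rescale it
#' in proportion to the pixel count for other tile sizes.
#'
#' @param height,width tile size in pixels.
#' @param n_tiles number of tiles.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @param background_level background intensity per channel (recycled),
#'   in 0..`bit_depth_max`.
#' @param vignette_strength corner attenuation in `[0, 1)`: the noise-free
#'   corner/center intensity ratio is `1 - vignette_strength`.
#' @param fixed_pattern_sd relative sd of the static per-pixel multiplicative
#'   gain (lognormal, mean 1), drawn once per field.
#' @param object_density expected number of elliptical objects per tile
#'   (Poisson).
#' @param object_attenuation multiplicative darkening inside an object, in
#'   `(0, 1]`.
#' @param artifact_rate fraction of tiles carrying a dust/bubble artifact;
#'   exactly `ceiling(artifact_rate * n_tiles)` tiles are affected.
#' @param photon_noise_sd relative sd of the per-acquisition multiplicative
#'   noise, drawn independently per tile (this is the temporal noise the
#'   method does not model, as opposed to the recoverable fixed pattern).
#' @param bit_depth_max peak intensity (255 for 8-bit).
#' @param seed integer seed freezing the whole collection.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(height = 256L, width = 256L, n_tiles = 100L,
                         channels = 3L, background_level = 200,
                         vignette_strength = 0.3, fixed_pattern_sd = 0.02,
                         object_density = 28, object_attenuation = 0.5,
                         artifact_rate = 0.1, photon_noise_sd = 0.01,
                         bit_depth_max = 255, seed = 1L) {
  cfg <- list(
    height = as.integer(height), width = as.integer(width),
    n_tiles = as.integer(n_tiles), channels = as.integer(channels),
    background_level = rep_len(as.numeric(background_level), as.integer(channels)),
    vignette_strength = vignette_strength, fixed_pattern_sd = fixed_pattern_sd,
    object_density = object_density, object_attenuation = object_attenuation,
    artifact_rate = artifact_rate, photon_noise_sd = photon_noise_sd,
    bit_depth_max = bit_depth_max, seed = as.integer(seed)
  )
  if (cfg$height < 1 || cfg$width < 1 || cfg$n_tiles < 1) {
    abort_parameter("height, width and n_tiles must be positive")
  }
  if (!cfg$channels %in% c(1L, 3L)) abort_parameter("channels must be 1 or 3")
  if (cfg$vignette_strength < 0 || cfg$vignette_strength >= 1) {
    abort_parameter("vignette_strength must be in [0, 1)")
  }
  if (any(cfg$background_level * (1 - cfg$vignette_strength) <= 0)) {
    abort_parameter("background must stay positive after vignetting")
  }
  if (cfg$fixed_pattern_sd < 0 || cfg$photon_noise_sd < 0) {
    abort_parameter("noise standard deviations must be nonnegative")
  }
  if (cfg$object_attenuation <= 0 || cfg$object_attenuation > 1) {
    abort_parameter("object_attenuation must be in (0, 1]")
  }
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1) {
    abort_parameter("artifact_rate must be in [0, 1]")
  }
  if (cfg$object_density < 0) abort_parameter("object_density must be nonnegative")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(
    "<synth_config> %d tiles of %d x %d x %d, background %s, vignette %g, fpn sd %g, seed %d\n",
    x$n_tiles, x$height, x$width, x$channels,
    paste(x$background_level, collapse = "/"), x$vignette_strength,
    x$fixed_pattern_sd, x$seed
  ))
  invisible(x)
}

#' Simulate the ground-truth flat field
#'
#' `F(k) = background_level * vignette(k) * gain(k)` with a radial
#' cosine-squared vignette, `vignette(k) = 1 - s * sin^2(pi/2 * rho(k))`
#' where `rho` is the distance from the tile center normalized so the
#' corners sit at 1 (hence a closed-form corner/center ratio of `1 - s`),
#' and a static per-pixel lognormal gain with mean 1 and sd
#' `fixed_pattern_sd`, frozen by the seed. The gain is drawn once per field
#' and shared by all tiles — that is what makes it fixed-pattern rather than
#' temporal noise.
#'
#' @param config a [synth_config()].
#' @return A `flat_field_model` holding the true field (no smoothness
#'   profile, `selected_rank` `NA`).
#' @export
make_flat_field <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  H <- config$height; W <- config$width; C <- config$channels
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r_corner <- sqrt((H - cy)^2 + (W - cx)^2)
  if (r_corner == 0) r_corner <- 1
  rho <- sqrt(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`)) / r_corner
  vignette <- 1 - config$vignette_strength * sin(pi / 2 * pmin(rho, 1))^2
  gain <- withr_seed(config$seed, {
    if (config$fixed_pattern_sd > 0) {
      sdlog <- sqrt(log(1 + config$fixed_pattern_sd^2))
      array(stats::rlnorm(H * W * C, meanlog = -sdlog^2 / 2, sdlog = sdlog),
            dim = c(H, W, C))
    } else {
      array(1, dim = c(H, W, C))
    }
  })
  field <- array(0, dim = c(H, W, C))
  for (c in seq_len(C)) {
    field[, , c] <- config$background_level[c] * vignette * gain[, , c]
  }
  new_flat_field_model(field, rep(NA_integer_, C), NULL, config$bit_depth_max)
}

#' Simulate a tile collection with ground truth
#'
#' Realizes the forward image-formation model `Y_i = X_i * F * (1 + noise)`
#' with zero dark field. The content `X_i` is background at transmittance
#' 1.0 with Poisson-many darker elliptical objects; a fixed number of tiles
#' (`ceiling(artifact_rate * n)`) additionally carry an artifact — bright
#' bubble rings and dark dust specks, alternating — stamped into the content
#' before multiplication by the field, so bright artifacts surface in the
#' low (bright) rank candidates exactly as slide contamination does.
#' Observed intensities are clamped to `[0, bit_depth_max]` (sensor
#' saturation).
#'
#' @param config a [synth_config()].
#' @return A list with `observed` (the distorted [tile_stack()] `Y`),
#'   `truth_content` (`X` on the transmittance scale, background = 1),
#'   `truth_stack` (`X` rescaled per channel by the spatial mean of the true
#'   field — ground truth on the same intensity scale as a `preserve_mean`
#'   correction), `truth_field` (the `flat_field_model` used), and
#'   `artifact_tiles` (indices of tiles carrying artifacts).
#' @export
make_collection <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  H <- config$height; W <- config$width; C <- config$channels; n <- config$n_tiles
  truth_field <- make_flat_field(config)
  n_art <- if (config$artifact_rate > 0) as.integer(ceiling(config$artifact_rate * n)) else 0L
  artifact_tiles <- withr_seed((config$seed + 104729L) %% .Machine$integer.max, {
    if (n_art > 0) sort(sample.int(n, n_art)) else integer(0)
  })
  content <- array(0, dim = c(H, W, C, n))
  observed <- array(0, dim = c(H, W, C, n))
  fvec <- as.vector(truth_field$field)
  for (i in seq_len(n)) {
    tile_seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    x <- withr_seed(tile_seed, {
      xi <- make_content_plane(H, W, config)
      if (i %in% artifact_tiles) {
        kind <- if (match(i, artifact_tiles) %% 2L == 1L) "bubble" else "dust"
        xi <- stamp_artifact(xi, kind)
      }
      xi
    })
    xc <- array(rep(x, C), dim = c(H, W, C))
    content[, , , i] <- xc
    noise <- withr_seed((tile_seed + 1L) %% .Machine$integer.max, {
      if (config$photon_noise_sd > 0) {
        array(1 + stats::rnorm(H * W * C, sd = config$photon_noise_sd), dim = c(H, W, C))
      } else {
        1
      }
    })
    y <- as.vector(xc) * fvec * as.vector(noise)
    observed[, , , i] <- pmin(pmax(y, 0), config$bit_depth_max)
  }
  dtype <- if (config$bit_depth_max >= 65535) "uint16" else "uint8"
  ch_means <- apply(truth_field$field, 3L, mean)
  truth_scaled <- content * rep(rep(ch_means, each = H * W), times = n)
  list(
    observed = tile_stack(observed, bit_depth_max = config$bit_depth_max,
                          dtype = dtype, allow_single = TRUE),
    truth_content = tile_stack(content, bit_depth_max = config$bit_depth_max,
                               dtype = "float", allow_single = TRUE),
    truth_stack = tile_stack(pmin(truth_scaled, config$bit_depth_max),
                             bit_depth_max = config$bit_depth_max,
                             dtype = dtype, allow_single = TRUE),
    truth_field = truth_field,
    artifact_tiles = artifact_tiles
  )
}

# one tile's content plane: background 1.0 with darker elliptical objects;
# uses the current RNG stream
make_content_plane <- function(H, W, config) {
  x <- matrix(1, H, W)
  n_obj <- if (config$object_density > 0) stats::rpois(1, config$object_density) else 0L
  if (n_obj == 0L) return(x)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (j in seq_len(n_obj)) {
    cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
    a <- stats::runif(1, 6, 20); b <- stats::runif(1, 6, 20)
    th <- stats::runif(1, 0, pi)
    dr <- rows - cy; dc <- cols - cx
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    x[inside] <- x[inside] * config$object_attenuation
  }
  x
}

# bubbles are bright rings, dust specks small dark disks; both part of the
# slide content, so they belong in the ground truth too
stamp_artifact <- function(x, kind = c("bubble", "dust")) {
  kind <- match.arg(kind)
  H <- nrow(x); W <- ncol(x)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  cy <- stats::runif(1, H * 0.2, H * 0.8)
  cx <- stats::runif(1, W * 0.2, W * 0.8)
  d <- sqrt((rows - cy)^2 + (cols - cx)^2)
  if (kind == "bubble") {
    r0 <- stats::runif(1, min(H, W) * 0.08, min(H, W) * 0.18)
    ring <- abs(d - r0) <= max(2, r0 * 0.12)
    x[ring] <- x[ring] * 1.25
    inside <- d < r0 - max(2, r0 * 0.12)
    x[inside] <- x[inside] * 1.05
  } else {
    r0 <- stats::runif(1, 2, 6)
    x[d <= r0] <- x[d <= r0] * 0.15
  }
  x
}

#' Simulate an empty-slide collection
#'
#' Empty-slide acquisitions observe the flat field directly:
#' `Y_i = F * (1 + noise)` with no objects or artifacts. Used to exercise
#' the empty-zero reference estimator against the known field.
#'
#' @param config a [synth_config()]; `photon_noise_sd` and the field
#'   parameters apply, object/artifact settings are ignored.
#' @param n number of empty tiles (default `config$n_tiles`).
#' @return A list with `observed` (the empty [tile_stack()]) and
#'   `truth_field`.
#' @export
make_empty_collection <- function(config, n = config$n_tiles) {
  stopifnot(inherits(config, "synth_config"))
  H <- config$height; W <- config$width; C <- config$channels
  truth_field <- make_flat_field(config)
  fvec <- as.vector(truth_field$field)
  observed <- array(0, dim = c(H, W, C, n))
  for (i in seq_len(n)) {
    noise <- withr_seed((config$seed + 7919L * i + 3L) %% .Machine$integer.max, {
      if (config$photon_noise_sd > 0) {
        1 + stats::rnorm(H * W * C, sd = config$photon_noise_sd)
      } else {
        rep(1, H * W * C)
      }
    })
    observed[, , , i] <- pmin(pmax(fvec * noise, 0), config$bit_depth_max)
  }
  dtype <- if (config$bit_depth_max >= 65535) "uint16" else "uint8"
  list(
    observed = tile_stack(observed, bit_depth_max = config$bit_depth_max,
                          dtype = dtype, allow_single = TRUE),
    truth_field = truth_field
  )
}

#' Read / write a synthetic configuration as YAML
#'
#' @param path YAML file with any subset of [synth_config()] fields.
#' @return `read_synth_config()`: a `synth_config`.
#' @export
read_synth_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_parameter(sprintf("unknown config field(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  do.call(synth_config, vals)
}

#' @rdname read_synth_config
#' @param config a [synth_config()] to write.
#' @export
write_synth_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
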