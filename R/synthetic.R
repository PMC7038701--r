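# Seeded synthetic depth scenes with the statistical structure the
# depth-density method assumes: smooth within-object depth gradients, a
# band of zero-valued (no-return) pixels along object boundaries, additive
# Gaussian sensor noise, and segmentation masks corrupted the way a coarse
# convolutional segmenter fails (blurred boundary + isolated misclassified
# pixels). Everything is deterministic given the seed.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Synthetic smooth-gradient surface patch
#'
#' Depth patch emulating a continuous object surface: a linear ramp
#' `base + slope * (row + col)` (0-based indices) plus optional i.i.d.
#' Gaussian sensor noise, clipped to `[0, 1]`.
#'
#' @param side patch side, `>= 3`.
#' @param slope per-pixel depth gradient (normalized units), default 0.002.
#' @param noise_sd Gaussian noise standard deviation, default 0.01.
#' @param base depth at the top-left pixel.
#' @param seed integer seed; the patch is deterministic given it.
#' @return `side`-square numeric matrix in `[0, 1]`.
#' @export
make_surface_patch <- function(side, slope = 0.002, noise_sd = 0.01,
                               base = 0.3, seed = NULL) {
  side <- as.integer(side)
  if (is.na(side) || side < 3L) stop_invalid("side must be >= 3")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  idx <- 0:(side - 1L)
  patch <- outer(idx, idx, function(r, c) base + slope * (r + c))
  if (noise_sd > 0)
    patch <- patch + with_seed(seed, matrix(stats::rnorm(side^2, 0, noise_sd),
                                            side, side))
  pmin(pmax(patch, 0), 1)
}

#' Synthetic two-level boundary patch with a no-return band
#'
#' Depth patch emulating the boundary between two objects as seen by a
#' time-of-flight sensor: left half at `low`, right half at `high`, and a
#' centred vertical band of exactly-zero pixels (the sensor's no-return
#' shadow) of width `zero_band_width`.
#'
#' @param side patch side, `>= 3`.
#' @param low,high the two depth levels, `high - low >= 0.2`.
#' @param zero_band_width width in pixels of the zero band, `>= 0`.
#' @param noise_sd optional Gaussian noise added to the non-zero levels.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return `side`-square numeric matrix in `[0, 1]`.
#' @export
make_boundary_patch <- function(side, low = 0.3, high = 0.7,
                                zero_band_width = 2L, noise_sd = 0,
                                seed = NULL) {
  side <- as.integer(side)
  if (is.na(side) || side < 3L) stop_invalid("side must be >= 3")
  if (high - low < 0.2) stop_invalid("high - low must be >= 0.2")
  zero_band_width <- as.integer(zero_band_width)
  if (zero_band_width < 0L) stop_invalid("zero_band_width must be >= 0")
  m <- matrix(low, side, side)
  m[, (side %/% 2L + 1L):side] <- high
  if (noise_sd > 0) {
    m <- m + with_seed(seed, matrix(stats::rnorm(side^2, 0, noise_sd),
                                    side, side))
    m <- pmin(pmax(m, 0), 1)
  }
  if (zero_band_width > 0L) {
    first <- side %/% 2L - zero_band_width %/% 2L + 1L
    m[, first:(first + zero_band_width - 1L)] <- 0
  }
  m
}

#' Specification of a synthetic depth scene
#'
#' Bundles the parameters of [make_scene()]. Defaults describe the kind of
#' scene the refinement targets: a single foreground object (label 1)
#' nearer the camera than a flat background, a gentle depth gradient across
#' the object surface, a 2-pixel no-return band hugging the object contour,
#' and mild sensor noise.
#'
#' @param height,width scene size in pixels.
#' @param object_shape `"ellipse"`, `"rectangle"` or `"blob"`.
#' @param object_depth,background_depth normalized depth levels; must differ
#'   by at least `depth_gap`.
#' @param depth_gap minimum required object/background separation.
#' @param surface_slope per-pixel gradient across the object surface.
#' @param noise_sd Gaussian sensor-noise standard deviation.
#' @param zero_band_width width of the no-return band along the contour.
#' @param object_extent object semi-axis as a fraction of the frame
#'   (`<= 0.45` so the object plus band fits).
#' @param seed integer seed making the whole scene reproducible.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(height = 96L, width = 96L,
                       object_shape = c("ellipse", "rectangle", "blob"),
                       object_depth = 0.35, background_depth = 0.75,
                       depth_gap = 0.3, surface_slope = 0.002,
                       noise_sd = 0.01, zero_band_width = 2L,
                       object_extent = 0.3, seed = 1L) {
  object_shape <- match.arg(object_shape)
  spec <- list(height = as.integer(height), width = as.integer(width),
               object_shape = object_shape, object_depth = object_depth,
               background_depth = background_depth, depth_gap = depth_gap,
               surface_slope = surface_slope, noise_sd = noise_sd,
               zero_band_width = as.integer(zero_band_width),
               object_extent = object_extent, seed = as.integer(seed))
  if (spec$height < 16L || spec$width < 16L)
    stop_invalid("scene must be at least 16 x 16")
  if (abs(object_depth - background_depth) < depth_gap)
    stop_invalid("|object_depth - background_depth| must be >= depth_gap")
  if (object_depth < 0 || object_depth > 1 ||
      background_depth < 0 || background_depth > 1)
    stop_invalid("depth levels must be in [0, 1]")
  if (noise_sd < 0 || spec$zero_band_width < 0L)
    stop_invalid("noise_sd and zero_band_width must be >= 0")
  if (object_extent <= 0 || object_extent > 0.45)
    stop_invalid("object does not fit in frame: object_extent must be in (0, 0.45]")
  class(spec) <- "scene_spec"
  spec
}

object_mask <- function(spec) {
  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  a <- spec$object_extent * w  # column semi-axis
  b <- spec$object_extent * h  # row semi-axis
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- switch(spec$object_shape,
    ellipse = ((cols - cx) / a)^2 + ((rows - cy) / b)^2 <= 1,
    rectangle = abs(cols - cx) <= a & abs(rows - cy) <= b,
    blob = {
      # ellipse with a smooth seeded radial perturbation (3 harmonics)
      ph <- with_seed(spec$seed + 7L, stats::runif(3, 0, 2 * pi))
      am <- with_seed(spec$seed + 11L, stats::runif(3, 0.05, 0.12))
      theta <- atan2((rows - cy) / b, (cols - cx) / a)
      rad <- sqrt(((cols - cx) / a)^2 + ((rows - cy) / b)^2)
      lim <- 1 + am[1] * sin(theta + ph[1]) + am[2] * sin(2 * theta + ph[2]) +
        am[3] * sin(3 * theta + ph[3])
      rad <= lim
    })
  mask <- matrix(0L, h, w)
  mask[inside] <- 1L
  mask
}

#' Generate a synthetic depth scene with masks
#'
#' Builds a paired depth image, ground-truth mask and corrupted mask: the
#' object region sits at `object_depth` with a gentle within-object ramp,
#' the background at `background_depth`; a band of exactly-zero (no-return)
#' pixels of width `zero_band_width` follows the object contour; Gaussian
#' noise is added to non-zero pixels. The corrupted mask emulates a coarse
#' segmenter via [corrupt_mask()].
#'
#' @param spec a [scene_spec()].
#' @return a `scene_sample`: list with `depth`, `gt`, `corrupted`, `spec`.
#' @examples
#' sc <- make_scene(scene_spec(seed = 42))
#' mean(sc$gt)  # object area fraction
#' @export
make_scene <- function(spec = scene_spec()) {
  if (!inherits(spec, "scene_spec")) stop_invalid("spec must be a scene_spec")
  h <- spec$height; w <- spec$width
  gt <- object_mask(spec)

  rows <- matrix(0:(h - 1L), h, w)
  cols <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  depth <- matrix(spec$background_depth, h, w)
  ramp <- spec$object_depth + spec$surface_slope * (rows + cols)
  depth[gt == 1L] <- ramp[gt == 1L]
  if (spec$noise_sd > 0)
    depth <- depth + with_seed(spec$seed,
                               matrix(stats::rnorm(h * w, 0, spec$noise_sd),
                                      h, w))
  depth <- pmin(pmax(depth, 0), 1)
  if (spec$zero_band_width > 0L) {
    obj <- gt == 1L
    grow <- ceiling(spec$zero_band_width / 2)
    shrink <- floor(spec$zero_band_width / 2)
    outer_m <- EBImage::dilate(obj, EBImage::makeBrush(2L * grow + 1L, "diamond"))
    inner_m <- if (shrink > 0L)
      EBImage::erode(obj, EBImage::makeBrush(2L * shrink + 1L, "diamond"))
    else obj
    depth[outer_m & !inner_m] <- 0
  }
  corrupted <- corrupt_mask(gt, dilation_radius = 2L, speckle_rate = 0.02,
                            seed = spec$seed + 1L)
  structure(list(depth = depth, gt = gt, corrupted = corrupted, spec = spec),
            class = "scene_sample")
}

#' Corrupt a binary mask the way a coarse segmenter does
#'
#' Blurs the object boundary by morphological dilation or erosion (the
#' direction chosen by a seeded coin flip) with a disc of radius
#' `dilation_radius`, then flips each pixel independently with probability
#' `speckle_rate` (isolated misclassified pixels).
#'
#' @param gt binary (0/1) integer label matrix.
#' @param dilation_radius radius in pixels of the boundary blur; 0 disables.
#' @param speckle_rate per-pixel flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return corrupted integer mask, same size as `gt`.
#' @export
corrupt_mask <- function(gt, dilation_radius = 2L, speckle_rate = 0.02,
                         seed = NULL) {
  check_label_mask(gt, "gt")
  if (!all(gt %in% c(0L, 1L))) stop_invalid("gt must be binary (0/1)")
  dilation_radius <- as.integer(dilation_radius)
  if (dilation_radius < 0L) stop_invalid("dilation_radius must be >= 0")
  if (speckle_rate < 0 || speckle_rate > 1)
    stop_invalid("speckle_rate must be in [0, 1]")
  out <- matrix(as.integer(gt), nrow(gt), ncol(gt))
  with_seed(seed, {
    if (dilation_radius > 0L) {
      brush <- EBImage::makeBrush(2L * dilation_radius + 1L, "disc")
      obj <- out == 1L
      obj <- if (stats::runif(1) < 0.5) EBImage::dilate(obj, brush)
             else EBImage::erode(obj, brush)
      out <- matrix(as.integer(obj), nrow(gt), ncol(gt))
    }
    if (speckle_rate > 0) {
      flip <- matrix(stats::runif(length(out)) < speckle_rate,
                     nrow(gt), ncol(gt))
      out[flip] <- 1L - out[flip]
    }
  })
  out
}

#' @export
print.scene_sample <- function(x, ...) {
  cat(sprintf("synthetic scene %d x %d (%s), seed %d\n", x$spec$height,
              x$spec$width, x$spec$object_shape, x$spec$seed))
  cat(sprintf("  object depth %.2f, background %.2f, noise sd %.3f, band %d px\n",
              x$spec$object_depth, x$spec$background_depth, x$spec$noise_sd,
              x$spec$zero_band_width))
  invisible(x)
}
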