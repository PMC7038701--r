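# Core depth-density operator.
#
# For a pixel (r, c) of a normalized depth image D, statistics are taken
# over the s-by-s window K centred there (out-of-image positions read as 0,
# the "no return" value):
#
#   d-bar      = mean of K                        (local mean)
#   sigma-bar  = sqrt(mean (d_ij - d-bar)^2)      (deviation about the mean)
#   sigma-prim = sqrt(mean (d_ij - d_rc)^2)       (deviation about the centre)
#
# and the depth density is the window mean of the peak-normalized product of
# two Gaussian scores,
#
#   dd_rc = mean_ij G(a_ij, d-bar, sigma-bar) * G(b_ij, d_rc, sigma-prim)
#           ---------------------------------------------------------------
#           ( max[ G(d-bar, d-bar, sigma-bar), G(d_rc, d_rc, sigma-prim) ] )^2
#
# clipped to [0, 1]. The original variant (v1) scores the neighbour depths
# directly, a_ij = b_ij = d_ij. The distance-weighted variant (v2) first
# shrinks each neighbour's deviation toward its reference by the "pixel
# distance difference" |deviation| / dist_ij (Manhattan distance from the
# centre), i.e. the deviation is scaled by (1 - 1/dist); the centre pixel
# (dist = 0) is left untouched. Uniform windows (both deviations below
# sigma_floor) are maximal same-surface evidence and score exactly 1.

#' Gaussian density
#'
#' The standard normal density used by the depth-density operator.
#' Degenerate `sigma` is the caller's responsibility (see `sigma_floor`
#' in [depth_density()]).
#'
#' @param x,mu,sigma evaluation point, mean and standard deviation
#'   (vectorized; `sigma > 0`).
#' @return density values `exp(-(x-mu)^2/(2 sigma^2)) / (sigma sqrt(2 pi))`.
#' @examples
#' gauss(1, 0, 1)   # 0.2419707
#' @export
gauss <- function(x, mu, sigma) {
  exp(-(x - mu)^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

#' Manhattan distance between window offsets
#'
#' @param di,dj integer row/column offsets from the window centre.
#' @return `|di| + |dj|` (vectorized).
#' @examples
#' manhattan_distance(-2, 3)  # 5
#' @export
manhattan_distance <- function(di, dj) abs(di) + abs(dj)

#' Pixel distance difference within a window
#'
#' Depth deviation of each window cell from a reference, divided by the
#' cell's Manhattan distance from the window centre. Far neighbours are
#' down-weighted; at the centre (distance 0) both values are defined as 0.
#'
#' @param window s-by-s numeric matrix of depths (s odd).
#' @param center_value depth of the centre pixel.
#' @param window_mean mean depth of the window.
#' @return list with s-by-s matrices `dif_mean` (`|d_ij - mean| / dist`) and
#'   `dif_center` (`|d_ij - center| / dist`).
#' @examples
#' w <- matrix(0.2, 3, 3); w[1, 1] <- 0.8
#' pixel_distance_difference(w, 0.2, mean(w))$dif_center[1, 1]  # 0.6 / 2
#' @export
pixel_distance_difference <- function(window, center_value, window_mean) {
  if (!is.matrix(window) || nrow(window) != ncol(window) ||
      nrow(window) %% 2L != 1L)
    stop_invalid("window must be a square matrix with odd side")
  half <- (nrow(window) - 1L) %/% 2L
  dist <- outer(abs(-half:half), abs(-half:half), `+`)
  safe <- pmax(dist, 1L)
  dm <- abs(window - window_mean) / safe
  dc <- abs(window - center_value) / safe
  dm[dist == 0L] <- 0
  dc[dist == 0L] <- 0
  list(dif_mean = dm, dif_center = dc)
}

# zero-pad by half on all sides
pad_zero <- function(img, half) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h + 2L * half, w + 2L * half)
  out[half + seq_len(h), half + seq_len(w)] <- img
  out
}

# view of the padded image shifted by (di, dj), same size as the original
shift_view <- function(pad, h, w, half, di, dj) {
  pad[half + di + seq_len(h), half + dj + seq_len(w), drop = FALSE]
}

#' Local window statistics of a depth image
#'
#' Per-pixel mean, deviation about the mean and deviation about the centre
#' pixel over the s-by-s window centred at each pixel. Windows reaching past
#' the image read 0 (the no-return value), and all divisors are `s^2`
#' (population statistics).
#'
#' @param img numeric matrix of normalized depths in `[0, 1]`.
#' @param s odd window side length, `>= 3`.
#' @return list of h-by-w matrices `mean`, `sd_mean`, `sd_center`.
#' @export
local_stats <- function(img, s = 7L) {
  check_depth_image(img)
  s <- check_window_size(s)
  h <- nrow(img); w <- ncol(img); half <- (s - 1L) %/% 2L
  pad <- pad_zero(img, half)
  s1 <- matrix(0, h, w); s2 <- matrix(0, h, w)
  for (di in -half:half) for (dj in -half:half) {
    v <- shift_view(pad, h, w, half, di, dj)
    s1 <- s1 + v
    s2 <- s2 + v * v
  }
  m <- s1 / s^2
  e2 <- s2 / s^2
  list(
    mean = m,
    sd_mean = sqrt(pmax(e2 - m^2, 0)),
    sd_center = sqrt(pmax(e2 - 2 * img * m + img^2, 0))
  )
}

new_depth_density_map <- function(values, s, variant) {
  structure(list(values = values, s = as.integer(s), variant = variant),
            class = "depth_density_map")
}

#' Per-pixel depth density of a depth image
#'
#' Scores every pixel of a normalized depth image by how consistent its
#' depth is with the s-by-s window around it: close to 1 on continuous
#' object surfaces, low at inter-object boundaries and no-return (zero)
#' bands. See the package vignette for the model.
#'
#' @param img numeric matrix of normalized depths in `[0, 1]`.
#' @param s odd window side length, `>= 3`; 7 balances noise suppression
#'   against boundary sharpness and is the operating default.
#' @param variant `"v2"` (default) applies the Manhattan-distance weighting
#'   of the pixel distance difference; `"v1"` is the unweighted original.
#' @param sigma_floor lower bound on the window deviations; windows with both
#'   deviations below it are uniform and score exactly 1.
#' @return a `depth_density_map`: list with `values` (h-by-w matrix in
#'   `[0, 1]`), `s`, and `variant`.
#' @seealso [depth_density_naive()] for the reference implementation,
#'   [refine_mask()] for using the map.
#' @examples
#' dd <- depth_density(make_surface_patch(32, seed = 1), s = 7)
#' range(dd$values)
#' @export
depth_density <- function(img, s = 7L, variant = c("v2", "v1"),
                          sigma_floor = 1e-12) {
  check_depth_image(img)
  s <- check_window_size(s)
  variant <- match.arg(variant)
  if (!is.numeric(sigma_floor) || sigma_floor <= 0)
    stop_invalid("sigma_floor must be > 0")
  h <- nrow(img); w <- ncol(img); half <- (s - 1L) %/% 2L

  st <- local_stats(img, s)
  degen <- st$sd_mean < sigma_floor & st$sd_center < sigma_floor
  sb <- pmax(st$sd_mean, sigma_floor)
  sc <- pmax(st$sd_center, sigma_floor)

  pad <- pad_zero(img, half)
  num <- matrix(0, h, w)
  for (di in -half:half) for (dj in -half:half) {
    v <- shift_view(pad, h, w, half, di, dj)
    if (variant == "v2") {
      dist <- abs(di) + abs(dj)
      if (dist > 0L) {
        shrink <- 1 - 1 / dist
        a <- st$mean + (v - st$mean) * shrink
        b <- img + (v - img) * shrink
      } else {
        a <- v; b <- v
      }
    } else {
      a <- v; b <- v
    }
    num <- num + gauss(a, st$mean, sb) * gauss(b, img, sc)
  }
  num <- num / s^2
  den <- pmax(gauss(st$mean, st$mean, sb), gauss(img, img, sc))^2
  dd <- pmin(pmax(num / den, 0), 1)
  dd[degen] <- 1
  new_depth_density_map(dd, s, variant)
}

#' Reference (per-pixel loop) depth density
#'
#' Same contract as [depth_density()], computed by direct scalar loops over
#' pixels and window cells with no shared intermediates. Intended as an
#' independent cross-check on small images (roughly up to 64-by-64).
#'
#' @inheritParams depth_density
#' @param agg window aggregation of the per-cell Gaussian scores; `"mean"`
#'   is the operator's definition, the alternatives are an experimentation
#'   hook only.
#' @return a `depth_density_map` (see [depth_density()]).
#' @export
depth_density_naive <- function(img, s = 7L, variant = c("v2", "v1"),
                                sigma_floor = 1e-12,
                                agg = c("mean", "median", "sum")) {
  check_depth_image(img)
  s <- check_window_size(s)
  variant <- match.arg(variant)
  agg <- match.arg(agg)
  aggf <- switch(agg, mean = mean, median = stats::median, sum = sum)
  h <- nrow(img); w <- ncol(img); half <- (s - 1L) %/% 2L
  pad <- pad_zero(img, half)
  out <- matrix(NA_real_, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      win <- pad[r + half + (-half:half), c + half + (-half:half)]
      d <- img[r, c]
      mu <- sum(win) / s^2
      sb <- sqrt(sum((win - mu)^2) / s^2)
      sp <- sqrt(sum((win - d)^2) / s^2)
      if (sb < sigma_floor && sp < sigma_floor) {
        out[r, c] <- 1
        next
      }
      sb <- max(sb, sigma_floor)
      sp <- max(sp, sigma_floor)
      if (variant == "v2") {
        dif <- pixel_distance_difference(win, d, mu)
        a <- win - sign(win - mu) * dif$dif_mean
        b <- win - sign(win - d) * dif$dif_center
      } else {
        a <- win; b <- win
      }
      num <- aggf(gauss(a, mu, sb) * gauss(b, d, sp))
      den <- max(gauss(mu, mu, sb), gauss(d, d, sp))^2
      out[r, c] <- min(max(num / den, 0), 1)
    }
  }
  new_depth_density_map(out, s, variant)
}

#' @export
as.matrix.depth_density_map <- function(x, ...) x$values

#' @export
print.depth_density_map <- function(x, ...) {
  cat(sprintf("depth density map: %d x %d, s = %d, variant = %s\n",
              nrow(x$values), ncol(x$values), x$s, x$variant))
  cat(sprintf("  range [%.4f, %.4f], median %.4f\n",
              min(x$values), max(x$values), stats::median(x$values)))
  invisible(x)
}

#' Display a depth-density map
#'
#' @param x a `depth_density_map`.
#' @param colormap a palette name accepted by [grDevices::hcl.colors()].
#' @param ... passed on to [graphics::image()].
#' @export
plot.depth_density_map <- function(x, colormap = "viridis", ...) {
  v <- x$values
  graphics::image(t(v)[, nrow(v):1, drop = FALSE], zlim = c(0, 1),
                  col = grDevices::hcl.colors(256, colormap), axes = FALSE,
                  asp = nrow(v) / ncol(v), ...)
  invisible(x)
}
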