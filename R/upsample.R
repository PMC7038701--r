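# Up-sampling operators used to grow coarse class heat maps back to input
# resolution: "valid"-mode bilinear doubling and "full"-mode de-convolution,
# plus the alternating schedule that chains them with optional skip maps.
# Shapes are the contract; kernel values are the conventional interpolating
# defaults and can be overridden in deconv_full().

# sliding cross-correlation, no padding ("valid")
conv_valid <- function(x, k) {
  kn <- nrow(k)
  out_side <- nrow(x) - kn + 1L
  out <- matrix(0, out_side, out_side)
  for (a in seq_len(kn)) for (b in seq_len(kn)) {
    out <- out + k[a, b] * x[(a - 1L) + seq_len(out_side),
                             (b - 1L) + seq_len(out_side), drop = FALSE]
  }
  out
}

check_feature_map <- function(fm, arg = "fm") {
  if (!is.matrix(fm) || !is.numeric(fm) || nrow(fm) != ncol(fm) ||
      nrow(fm) < 1L)
    stop_invalid(arg, " must be a square numeric matrix")
  invisible(fm)
}

#' Separable triangular (bilinear-interpolation) kernel
#'
#' @param m kernel side, `>= 2`.
#' @return m-by-m matrix, outer product of a unit-peak triangle.
#' @export
bilinear_kernel <- function(m) {
  if (m < 2L) stop_invalid("kernel side must be >= 2")
  v <- pmin(seq_len(m), rev(seq_len(m)))
  v <- v / max(v)
  outer(v, v)
}

#' Valid-mode bilinear up-sampling (side N to 2N)
#'
#' Interleaves the feature map with zeros onto a `(2N+1)`-sided grid
#' (original values at odd 1-based positions) and convolves with the fixed
#' 2-by-2 averaging kernel (all ones / 4) in "valid" mode, doubling the side.
#'
#' @param fm square numeric feature map.
#' @return feature map of side `2 * nrow(fm)`.
#' @examples
#' dim(bilinear_valid(matrix(1, 2, 2)))  # 4 x 4
#' @export
bilinear_valid <- function(fm) {
  check_feature_map(fm)
  n <- nrow(fm)
  z <- matrix(0, 2L * n + 1L, 2L * n + 1L)
  odd <- 2L * seq_len(n) - 1L
  z[odd, odd] <- fm
  conv_valid(z, matrix(1 / 4, 2L, 2L))
}

#' Full-mode de-convolution (side N to M + N - 1)
#'
#' Zero-pads the feature map by `M - 1` on all sides and convolves with an
#' M-by-M kernel, stride 1 ("full" mode), expanding side N to `M + N - 1`.
#' Sliding is cross-correlation, so a 1-by-1 impulse reproduces the kernel
#' rotated by 180 degrees (the convolution convention); the default kernel
#' is symmetric, making the distinction unobservable.
#'
#' @param fm square numeric feature map.
#' @param k M-by-M kernel, `M >= 2`; default [bilinear_kernel()] of side `m`.
#' @param m kernel side used when `k` is not given.
#' @return feature map of side `nrow(k) + nrow(fm) - 1`.
#' @examples
#' dim(deconv_full(matrix(1, 1, 1), m = 2))  # 2 x 2
#' @export
deconv_full <- function(fm, k = bilinear_kernel(m), m = 2L) {
  check_feature_map(fm)
  check_feature_map(k, "k")
  if (nrow(k) < 2L) stop_invalid("kernel side must be >= 2")
  mm <- nrow(k)
  conv_valid(pad_zero(fm, mm - 1L), k)
}

#' Alternating de-convolution / bilinear up-sampling schedule
#'
#' Grows a coarse heat map to `target_side` by alternating full-mode
#' de-convolution and valid-mode bilinear doubling, starting with
#' de-convolution. Each de-convolution step uses the doubling kernel size
#' `M = N + 1` so every stage doubles the side (a 1-sided map reaches 32 via
#' 1, 2, 4, 8, 16, 32). When `skips` are supplied, any skip map whose side
#' matches the current map is added element-wise before the next operation
#' (unweighted, enriching the heat map with encoder features). If the final
#' side overshoots `target_side`, the map is cropped top-left to size.
#'
#' @param heat square numeric heat map.
#' @param target_side desired output side, `>= nrow(heat)`.
#' @param skips optional list of square feature maps.
#' @return feature map of side `target_side`.
#' @export
upsample_schedule <- function(heat, target_side, skips = NULL) {
  check_feature_map(heat, "heat")
  target_side <- as.integer(target_side)
  if (is.na(target_side) || target_side < nrow(heat))
    stop_invalid("target_side must be >= the heat-map side")
  sides <- integer(0)
  if (!is.null(skips)) {
    for (sk in skips) check_feature_map(sk, "skip map")
    sides <- vapply(skips, nrow, integer(1))
  }
  used <- rep(FALSE, length(sides))
  add_skip <- function(x) {
    hit <- which(sides == nrow(x) & !used)
    for (i in hit) {
      x <- x + skips[[i]]
      used[i] <<- TRUE
    }
    x
  }
  x <- heat
  use_deconv <- TRUE
  while (nrow(x) < target_side) {
    x <- add_skip(x)
    x <- if (use_deconv) deconv_full(x, m = nrow(x) + 1L) else bilinear_valid(x)
    use_deconv <- !use_deconv
  }
  if (!all(used))
    stop_invalid("skip map of side ", sides[which(!used)[1L]],
                 " matches no intermediate feature map")
  x[seq_len(target_side), seq_len(target_side), drop = FALSE]
}
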