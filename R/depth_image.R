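#' depthdensity: depth-density refinement of semantic segmentation
#'
#' Computes a per-pixel "depth density" score from time-of-flight depth
#' images and uses it to refine coarse segmentation masks. See
#' `vignette("depth-density")` for the model and its assumptions.
#'
#' @keywords internal
"_PACKAGE"

# ---- validation helpers ----------------------------------------------------

stop_invalid <- function(...) stop(..., call. = FALSE)

check_depth_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_invalid(arg, " must be a numeric matrix")
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop_invalid(arg, " must have at least one row and one column")
  if (anyNA(img) || min(img) < 0 || max(img) > 1)
    stop_invalid(arg, " must contain finite values in [0, 1]")
  invisible(img)
}

check_window_size <- function(s) {
  if (length(s) != 1L || is.na(s) || s < 3L || s %% 2L != 1L)
    stop_invalid("window side length s must be an odd integer >= 3")
  as.integer(s)
}

check_label_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop_invalid(arg, " must be an integer matrix")
  if (anyNA(mask) || any(mask < 0) || any(mask != round(mask)))
    stop_invalid(arg, " must contain non-negative integer class IDs")
  invisible(mask)
}

#' Normalize raw depth (millimetres) to the unit interval
#'
#' Maps raw time-of-flight depth readings in millimetres onto normalized
#' depth in `[0, 1]` by linear rescaling over an acquisition range,
#' clipping values outside the range. A raw value of exactly 0 is the
#' sensor's "no return" sentinel and maps to exactly 0 regardless of
#' `d_min`. Defaults correspond to a working range of 0.5-4.5 m.
#'
#' @param raw numeric vector or matrix of raw depths in mm, all `>= 0`.
#' @param d_min,d_max acquisition range in mm, `d_min < d_max`.
#' @return object of the same shape as `raw` with values in `[0, 1]`.
#' @examples
#' normalize_depth(c(0, 500, 2500, 4500))
#' @export
normalize_depth <- function(raw, d_min = 500, d_max = 4500) {
  if (!is.numeric(raw) || anyNA(raw) || min(raw) < 0)
    stop_invalid("raw must be numeric and >= 0")
  if (!is.numeric(d_min) || !is.numeric(d_max) || d_min >= d_max)
    stop_invalid("invalid depth range: d_min must be < d_max")
  out <- pmin(pmax((raw - d_min) / (d_max - d_min), 0), 1)
  out[raw == 0] <- 0
  out
}
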