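# Threshold-based refinement of a coarse segmentation mask using the
# depth-density map. Single pass over the INPUT mask (order-independent):
#   dd <  low   -> background (boundary / no-return / noise evidence)
#   dd >= high  -> majority label of the surrounding window in the input mask
#   otherwise   -> unchanged

#' Majority label of a window
#'
#' Most frequent label among the supplied window entries, optionally
#' excluding one occurrence set (the centre's label class is *not* excluded;
#' `exclude` removes a label class entirely). Ties break to the smallest
#' label ID so the result is deterministic.
#'
#' @param window_labels vector of non-negative integer labels.
#' @param exclude optional label class to drop before voting.
#' @param fallback label returned when nothing remains after exclusion.
#' @return the winning label as an integer.
#' @examples
#' majority_label(c(0, 0, 0, 0, 1, 1, 1, 1, 1))  # 1
#' majority_label(c(0, 0, 1, 1))                 # tie -> 0
#' @export
majority_label <- function(window_labels, exclude = NULL, fallback = NULL) {
  if (length(window_labels) == 0L)
    stop_invalid("window_labels must be non-empty")
  labs <- as.integer(window_labels)
  if (!is.null(exclude)) labs <- labs[labs != as.integer(exclude)]
  if (length(labs) == 0L) {
    if (is.null(fallback))
      stop_invalid("window empty after exclusion and no fallback given")
    return(as.integer(fallback))
  }
  counts <- tabulate(labs + 1L)
  which.max(counts) - 1L  # first max = smallest label ID
}

#' Refine a segmentation mask with a depth-density map
#'
#' Re-classifies pixels of a coarse mask using per-pixel depth density:
#' pixels whose density falls below `low` carry boundary/no-return evidence
#' and are set to `background`; pixels at or above `high` are confidently on
#' a surface and take the majority label of the `window`-sized neighbourhood
#' around them in the *input* mask (windows are clipped at image borders);
#' everything in between is left untouched. The input mask is not modified.
#'
#' @param mask integer matrix of class IDs (background = `background`).
#' @param dd a `depth_density_map` from [depth_density()], or a numeric
#'   matrix of densities in `[0, 1]`, same size as `mask`.
#' @param high,low density thresholds, `0 <= low < high <= 1`. Defaults are
#'   the operating points 0.9 and 0.15 (0.2 is a common alternate low cut).
#' @param window odd side of the majority-vote window; defaults to the
#'   window the density map was computed with (7 for plain matrices).
#' @param background background label, default 0.
#' @return refined mask, an integer matrix the same size as `mask`.
#' @examples
#' m <- matrix(1L, 9, 9); m[5, 5] <- 0L
#' dd <- matrix(0.95, 9, 9)
#' refine_mask(m, dd)[5, 5]  # speckle re-voted to 1
#' @export
refine_mask <- function(mask, dd, high = 0.9, low = 0.15, window = NULL,
                        background = 0L) {
  check_label_mask(mask)
  if (inherits(dd, "depth_density_map")) {
    if (is.null(window)) window <- dd$s
    dd <- dd$values
  }
  if (is.null(window)) window <- 7L
  window <- check_window_size(window)
  if (!is.matrix(dd) || !all(dim(dd) == dim(mask)))
    stop_invalid("mask and dd must have identical dimensions")
  if (anyNA(dd) || min(dd) < 0 || max(dd) > 1)
    stop_invalid("dd values must be in [0, 1]")
  if (!is.numeric(high) || !is.numeric(low) || low < 0 || high > 1 ||
      low >= high)
    stop_invalid("thresholds must satisfy 0 <= low < high <= 1")

  h <- nrow(mask); w <- ncol(mask); half <- (window - 1L) %/% 2L
  out <- matrix(as.integer(mask), h, w)
  vote <- which(dd >= high, arr.ind = TRUE)
  if (nrow(vote) > 0L) {
    for (k in seq_len(nrow(vote))) {
      r <- vote[k, 1L]; c <- vote[k, 2L]
      rows <- max(1L, r - half):min(h, r + half)
      cols <- max(1L, c - half):min(w, c + half)
      out[r, c] <- majority_label(mask[rows, cols], fallback = mask[r, c])
    }
  }
  out[dd < low] <- as.integer(background)
  out
}
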