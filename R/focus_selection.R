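#' Focus-filter parameters
#'
#' In-focus brightfield slices of a stained grain contain both deep shadows
#' (rim, pores) and a bright surround; defocused slices lose both extremes.
#' A slice is kept when its minimum intensity is at most
#' `min_pixel_threshold` AND its maximum is at least `max_pixel_threshold`.
#' `NULL` thresholds are resolved per grain from calibration-free percentiles
#' of the per-slice statistics (min threshold = 25th percentile of slice
#' minima, max threshold = 75th percentile of slice maxima), so the rule
#' adapts to bit depth and staining; these defaults are this package's
#' interpretation, not measured instrument values.
#'
#' @param min_pixel_threshold keep slices whose minimum is <= this.
#' @param max_pixel_threshold keep slices whose maximum is >= this.
#' @param min_kept_slices floor on the surviving slice count; when fewer
#'   slices pass, the `min_kept_slices` best-contrast slices are kept and a
#'   warning is issued.
#' @param method `"minmax"` (rule above) or `"contrast_percentile"` (keep
#'   slices whose contrast is at least `contrast_quantile` of the per-slice
#'   contrasts).
#' @param contrast_quantile quantile used by `"contrast_percentile"`.
#' @return An object of class `focus_params`.
#' @export
focus_params <- function(min_pixel_threshold = NULL,
                         max_pixel_threshold = NULL,
                         min_kept_slices = 3L,
                         method = c("minmax", "contrast_percentile"),
                         contrast_quantile = 0.5) {
  if (!is.null(min_pixel_threshold) && !is.null(max_pixel_threshold) &&
      is.finite(min_pixel_threshold) && is.finite(max_pixel_threshold))
    .assert(min_pixel_threshold < max_pixel_threshold,
            "min_pixel_threshold must be below max_pixel_threshold")
  .assert(min_kept_slices >= 1, "min_kept_slices must be >= 1")
  structure(list(min_pixel_threshold = min_pixel_threshold,
                 max_pixel_threshold = max_pixel_threshold,
                 min_kept_slices = as.integer(min_kept_slices),
                 method = match.arg(method),
                 contrast_quantile = contrast_quantile),
            class = "focus_params")
}

# evaluation mask: grain footprint dilated by the crop margin
focus_mask <- function(grain_stack) {
  m <- grain_stack$margin_px
  if (is.null(m) || m < 1) return(grain_stack$mask)
  kern <- EBImage::makeBrush(2L * as.integer(m) + 1L, "disc")
  as.matrix(EBImage::imageData(
    EBImage::dilate(EBImage::Image(grain_stack$mask * 1), kern))) > 0
}

#' Per-slice focus statistics of a grain sub-stack
#'
#' Minimum, maximum and contrast (max - min) of each slice, computed within
#' the grain mask dilated by the crop margin so surrounding background
#' contributes the bright extreme without distant clutter interfering.
#'
#' @param grain_stack a [extract_substack()] result.
#' @return Data frame with columns `slice`, `min`, `max`, `contrast`.
#' @export
slice_focus_stats <- function(grain_stack) {
  .assert(inherits(grain_stack, "grain_stack"), "need a grain_stack")
  d <- dim(grain_stack$voxels)
  .assert(d[3] >= 1, "empty stack")
  m <- focus_mask(grain_stack)
  if (!any(m)) m <- matrix(TRUE, d[1], d[2])
  stats <- t(vapply(seq_len(d[3]), function(s) {
    x <- grain_stack$voxels[, , s][m]
    c(min(x), max(x))
  }, numeric(2)))
  data.frame(slice = seq_len(d[3]), min = stats[, 1], max = stats[, 2],
             contrast = stats[, 2] - stats[, 1])
}

#' Remove out-of-focus slices from a grain sub-stack
#'
#' Applies the keep-rule of [focus_params()] to the per-slice statistics. If
#' fewer than `min_kept_slices` slices survive (e.g. a debris-occluded grain
#' with no sharp slice), the best-contrast slices are kept instead and a
#' warning is issued. Slice order is always preserved; the output is a
#' subsequence of the input slices.
#'
#' @param grain_stack a [extract_substack()] result.
#' @param params a [focus_params()].
#' @return The `grain_stack` with `voxels` reduced to the kept slices,
#'   `kept_slices` recording their original indices, and a per-slice keep
#'   log (columns `slice`, `min`, `max`, `contrast`, `kept`) as attribute
#'   `slice_log`.
#' @export
filter_slices <- function(grain_stack, params = focus_params()) {
  st <- slice_focus_stats(grain_stack)
  .assert(nrow(st) >= 1, "empty stack")
  if (params$method == "contrast_percentile") {
    keep <- st$contrast >= quantile(st$contrast, params$contrast_quantile)
  } else {
    min_thr <- params$min_pixel_threshold %||% quantile(st$min, 0.25)
    max_thr <- params$max_pixel_threshold %||% quantile(st$max, 0.75)
    keep <- st$min <= min_thr & st$max >= max_thr
  }
  if (sum(keep) < params$min_kept_slices) {
    warning(sprintf("only %d slice(s) passed the focus thresholds; keeping the %d best by contrast",
                    sum(keep), params$min_kept_slices), call. = FALSE)
    best <- order(st$contrast, decreasing = TRUE)[seq_len(min(params$min_kept_slices, nrow(st)))]
    keep <- seq_len(nrow(st)) %in% best
  }
  idx <- which(keep)
  out <- grain_stack
  out$voxels <- grain_stack$voxels[, , idx, drop = FALSE]
  out$kept_slices <- grain_stack$kept_slices[idx]
  st$kept <- keep
  attr(out, "slice_log") <- st
  out
}
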