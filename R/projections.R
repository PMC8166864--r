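get_vox <- function(x) {
  if (inherits(x, "grain_stack")) x$voxels
  else if (inherits(x, "zstack")) x$voxels
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a grain_stack, zstack or 3-D array", call. = FALSE)
}

proj_attrs <- function(img, x) {
  if (inherits(x, "grain_stack")) {
    attr(img, "offset") <- x$offset
    attr(img, "pixel_size_um") <- x$pixel_size_um
  } else if (inherits(x, "zstack")) {
    attr(img, "pixel_size_um") <- x$pixel_size_um
  }
  img
}

#' Standard-deviation projection
#'
#' Per-pixel sample standard deviation (n - 1 denominator) of the intensity
#' through the kept slices; positions that change strongly through the focal
#' series (rims, pores) appear bright. Set `population = TRUE` for the n
#' denominator.
#'
#' @param grain_stack a focus-filtered grain sub-stack (or any `zstack` /
#'   3-D array with at least 2 slices).
#' @param population use the population (n) denominator instead of n - 1.
#' @return 2-D numeric matrix.
#' @export
stddev_projection <- function(grain_stack, population = FALSE) {
  v <- get_vox(grain_stack)
  n <- dim(v)[3]
  .assert(n >= 2,
          "standard-deviation projection needs >= 2 slices; relax the focus filter (min_kept_slices) first")
  m <- rowMeans(v, dims = 2)
  ss <- rowSums((v - as.vector(m))^2, dims = 2)
  proj_attrs(sqrt(ss / (n - if (population) 0 else 1)), grain_stack)
}

#' Minimum-intensity projection
#'
#' Per-pixel minimum through the kept slices.
#'
#' @param grain_stack a grain sub-stack, `zstack` or 3-D array.
#' @return 2-D numeric matrix.
#' @export
min_projection <- function(grain_stack) {
  v <- get_vox(grain_stack)
  proj_attrs(min_projection_raw(v), grain_stack)
}

# per-slice focus score: Sobel gradient energy averaged over a local window
edof_focus_scores <- function(v, focus_window_px, smoothing_px) {
  sob <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  # clamp window and smoothing support to the crop size (odd, >= 1)
  w_max <- min(dim(v)[1], dim(v)[2])
  focus_window_px <- min(focus_window_px, w_max - (1 - w_max %% 2))
  if (smoothing_px > 0 && (2 * ceiling(3 * smoothing_px) + 1) > w_max)
    smoothing_px <- max((w_max %/% 2 - 1) / 6, 0)
  box <- matrix(1 / focus_window_px^2, focus_window_px, focus_window_px)
  scores <- array(0, dim = dim(v))
  for (s in seq_len(dim(v)[3])) {
    x <- EBImage::Image(v[, , s])
    gx <- EBImage::filter2(x, sob, boundary = "replicate")
    gy <- EBImage::filter2(x, t(sob), boundary = "replicate")
    sc <- gx^2 + gy^2
    if (focus_window_px > 1)
      sc <- EBImage::filter2(sc, box, boundary = "replicate")
    if (smoothing_px > 0)
      sc <- EBImage::gblur(sc, sigma = smoothing_px, boundary = "replicate")
    scores[, , s] <- as.matrix(EBImage::imageData(sc))
  }
  scores
}

#' Extended-depth-of-field projection
#'
#' For every pixel, a focus score (local Sobel gradient energy averaged over
#' a `focus_window_px` window, optionally Gaussian-smoothed with
#' `smoothing_px`) is computed on each slice; the output takes each pixel
#' from the slice where its score is highest (hard selection, ties broken
#' toward the earlier slice), so every output value exists somewhere in that
#' pixel's slice column.
#'
#' @param grain_stack a grain sub-stack, `zstack` or 3-D array.
#' @param focus_window_px side of the local averaging window (odd, >= 1).
#' @param smoothing_px Gaussian sigma regularizing the score volume before
#'   the argmax; 0 disables smoothing.
#' @return 2-D numeric matrix with the slice-index map as attribute
#'   `index_map`.
#' @export
edof_projection <- function(grain_stack, focus_window_px = 9L,
                            smoothing_px = 2) {
  v <- get_vox(grain_stack)
  n <- dim(v)[3]
  if (n == 1L) {
    out <- v[, , 1]
    attr(out, "index_map") <- matrix(1L, dim(v)[1], dim(v)[2])
    return(proj_attrs(out, grain_stack))
  }
  scores <- edof_focus_scores(v, focus_window_px, smoothing_px)
  idx <- apply(scores, c(1, 2), which.max)
  out <- matrix(0, dim(v)[1], dim(v)[2])
  for (s in seq_len(n)) {
    sel <- idx == s
    out[sel] <- v[, , s][sel]
  }
  attr(out, "index_map") <- idx
  proj_attrs(out, grain_stack)
}

minmax_normalize <- function(x) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(list(img = x * 0, lo = rng[1], hi = rng[2],
                                     constant = TRUE))
  list(img = (x - rng[1]) / diff(rng), lo = rng[1], hi = rng[2],
       constant = FALSE)
}

border_median <- function(x) {
  median(c(x[1, ], x[nrow(x), ], x[, 1], x[, ncol(x)]))
}

#' Compose the fixed-size three-channel classifier input
#'
#' Each projection is min-max normalized to `[0, 1]` independently, then
#' placed unscaled (no resampling, so the grain's physical size in pixels is
#' preserved) with the grain centroid at the frame centre; padding is filled
#' with the channel's background estimate (median of its border pixels).
#' Projections larger than the frame are an error, never downscaled, because
#' grain size is a class feature.
#'
#' @param stddev,min_int,edof the three projections of one grain (equal
#'   shapes; as returned by [stddev_projection()], [min_projection()],
#'   [edof_projection()]).
#' @param region the grain's [grain_region].
#' @param frame_px frame side length (default 276).
#' @param offset row/col of the crop origin in the parent frame (taken from
#'   the projection attributes when present).
#' @param pixel_size_um calibration (taken from attributes when present).
#' @return A [framed_image()]; normalization constants per channel are
#'   attached as attribute `normalization`.
#' @export
compose_frame <- function(stddev, min_int, edof, region, frame_px = 276L,
                          offset = NULL, pixel_size_um = NULL) {
  .assert(identical(dim(stddev), dim(min_int)) &&
            identical(dim(stddev), dim(edof)),
          "projections must share one shape")
  h <- nrow(stddev); w <- ncol(stddev)
  .assert(h <= frame_px && w <= frame_px,
          "grain exceeds frame (%d x %d > %d); grains are never downscaled",
          h, w, frame_px)
  offset <- offset %||% attr(stddev, "offset") %||% c(1, 1)
  pixel_size_um <- pixel_size_um %||% attr(stddev, "pixel_size_um") %||% NA_real_
  centroid_crop <- region$centroid - offset + 1
  centre <- (frame_px + 1) / 2
  r0 <- round(centre - centroid_crop[1]); c0 <- round(centre - centroid_crop[2])
  r0 <- min(max(r0, 0), frame_px - h); c0 <- min(max(c0, 0), frame_px - w)

  pixels <- array(0, dim = c(frame_px, frame_px, 3L))
  norm <- vector("list", 3)
  chans <- list(stddev, min_int, edof)
  for (k in 1:3) {
    nm <- minmax_normalize(chans[[k]])
    bg <- border_median(nm$img)
    plane <- matrix(bg, frame_px, frame_px)
    plane[r0 + seq_len(h), c0 + seq_len(w)] <- nm$img
    pixels[, , k] <- plane
    norm[[k]] <- list(lo = nm$lo, hi = nm$hi, background = bg,
                      constant = nm$constant)
  }
  names(norm) <- c("stddev", "min_intensity", "extended_focus")
  img <- framed_image(pixels, pixel_size_um = pixel_size_um,
                      grain_id = as.character(region$id),
                      frame_px = as.integer(frame_px))
  attr(img, "normalization") <- norm
  img
}

#' Project one grain sub-stack into a framed classifier input
#'
#' Convenience pipeline: focus-filter the sub-stack, build the three
#' projections, and compose the frame.
#'
#' @param grain_stack an [extract_substack()] result.
#' @param fparams a [focus_params()].
#' @param frame_px frame side length.
#' @param focus_window_px,smoothing_px EDoF parameters.
#' @return A [framed_image()]; the focus-filter slice log is attached as
#'   attribute `slice_log`.
#' @export
project_grain <- function(grain_stack, fparams = focus_params(),
                          frame_px = 276L, focus_window_px = 9L,
                          smoothing_px = 2) {
  gs <- filter_slices(grain_stack, fparams)
  img <- compose_frame(stddev_projection(gs), min_projection(gs),
                       edof_projection(gs, focus_window_px, smoothing_px),
                       gs$region, frame_px = frame_px)
  attr(img, "slice_log") <- attr(gs, "slice_log")
  img
}

#' Detect, extract and project every grain in a stack
#'
#' Runs the full per-stack half of the pipeline: detect grains, crop each
#' into a sub-stack, focus-filter, project, frame.
#'
#' @param stack a calibrated [zstack()].
#' @param dparams a [detection_params()].
#' @param fparams a [focus_params()].
#' @param margin_px crop margin around each grain.
#' @param frame_px frame side length.
#' @param focus_window_px,smoothing_px EDoF parameters.
#' @return List of [framed_image()]s; the detection rejection log is
#'   attached as attribute `rejections`.
#' @export
project_stack <- function(stack, dparams = detection_params(),
                          fparams = focus_params(), margin_px = 10L,
                          frame_px = 276L, focus_window_px = 9L,
                          smoothing_px = 2) {
  det <- detect_grains(stack, dparams)
  frames <- lapply(det, function(r)
    project_grain(extract_substack(stack, r, margin_px), fparams,
                  frame_px, focus_window_px, smoothing_px))
  structure(frames, rejections = rejection_log(det))
}
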