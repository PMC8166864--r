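#' Detection parameters
#'
#' Defaults implement the standard reference-library filters: keep rounded
#' objects with circularity above 0.3 and an equivalent circular diameter
#' larger than 5 um, and drop anything touching the frame edge.
#'
#' @param circularity_min minimum circularity `4*pi*area/perimeter^2`,
#'   in `(0, 1]`.
#' @param diameter_min_um minimum equivalent circular diameter in um.
#' @param binarization_method `"otsu"` or `"fixed"` (see [binarize()]).
#' @param binarization_reference `"min_projection"` (binarize the
#'   minimum-intensity projection of the stack; grains are dark in at least
#'   one slice) or `"slice_union"` (union of per-slice masks).
#' @param exclude_border drop regions touching the frame edge.
#' @param fixed_threshold threshold used when `binarization_method = "fixed"`.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(circularity_min = 0.3, diameter_min_um = 5,
                             binarization_method = "otsu",
                             binarization_reference = "min_projection",
                             exclude_border = TRUE, fixed_threshold = 0.5) {
  .assert(circularity_min > 0 && circularity_min <= 1,
          "circularity_min must be in (0, 1]")
  .assert(diameter_min_um > 0, "diameter_min_um must be positive")
  .assert(binarization_reference %in% c("min_projection", "slice_union"),
          "unknown binarization_reference")
  structure(list(circularity_min = circularity_min,
                 diameter_min_um = diameter_min_um,
                 binarization_method = binarization_method,
                 binarization_reference = binarization_reference,
                 exclude_border = isTRUE(exclude_border),
                 fixed_threshold = fixed_threshold),
            class = "detection_params")
}

#' Binarize a reference image into candidate-grain foreground
#'
#' Foreground is the dark side of the threshold (stained grains on a bright
#' background); set `dark_foreground = FALSE` for inverted-polarity images.
#' The raw threshold mask is cleaned with hole filling and one 3x3 opening.
#' A constant image yields an empty mask, not an error. The method and the
#' computed threshold are attached as attributes (and appear in logs).
#'
#' @param image 2-D numeric matrix with finite values in `[0, 1]`.
#' @param method `"otsu"` (data-driven global threshold) or `"fixed"`.
#' @param dark_foreground are grains darker than the background?
#' @param fixed_threshold threshold for `method = "fixed"`.
#' @return Logical matrix with attributes `method` and `threshold`.
#' @export
binarize <- function(image, method = "otsu", dark_foreground = TRUE,
                     fixed_threshold = 0.5) {
  .assert(is.matrix(image) && all(is.finite(image)),
          "image must be a finite numeric matrix")
  x <- if (dark_foreground) image else 1 - image
  if (diff(range(x)) < 1e-12) {
    mask <- matrix(FALSE, nrow(x), ncol(x))
    return(structure(mask, method = method, threshold = NA_real_))
  }
  thr <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(pmin(pmax(x, 0), 1)), range = c(0, 1)),
    fixed = fixed_threshold,
    stop("unknown binarization method: ", method, call. = FALSE))
  fg <- EBImage::Image((x < thr) * 1)
  fg <- EBImage::fillHull(fg)
  fg <- EBImage::opening(fg, EBImage::makeBrush(3, "box"))
  structure(as.matrix(fg) > 0, method = method, threshold = as.numeric(thr))
}

# polygon length of the traced object boundary; axial steps count 1,
# diagonal steps sqrt(2) (chain-code estimator, named in rejection logs)
chain_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (length(oc) == 0) return(0)
  per <- 0
  for (ctr in oc) {
    if (nrow(ctr) < 2) { per <- per + 4; next } # isolated pixel: unit square
    d <- rbind(diff(ctr), ctr[1, ] - ctr[nrow(ctr), ])
    per <- per + sum(sqrt(rowSums(d^2)))
  }
  per
}

measure_region <- function(mask_crop, bbox, pixel_size_um, id) {
  area_px <- sum(mask_crop)
  per_px <- chain_perimeter(mask_crop)
  idx <- which(mask_crop, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]) + bbox[1] - 1, mean(idx[, 2]) + bbox[2] - 1)
  structure(list(id = id,
                 mask = mask_crop,
                 bbox = bbox,
                 centroid = centroid,
                 area_um2 = area_px * pixel_size_um^2,
                 equivalent_diameter_um = 2 * sqrt(area_px / pi) * pixel_size_um,
                 perimeter_um = per_px * pixel_size_um,
                 circularity = if (per_px > 0) 4 * pi * area_px / per_px^2 else 0,
                 perimeter_estimator = "chain-code (1, sqrt(2))"),
            class = "grain_region")
}

#' @export
print.grain_region <- function(x, ...) {
  cat(sprintf("<grain_region %s> centroid (%.1f, %.1f), d = %.2f um, circ = %.3f\n",
              x$id, x$centroid[1], x$centroid[2],
              x$equivalent_diameter_um, x$circularity))
  invisible(x)
}

#' Detect complete, non-overlapping pollen grains in a Z-stack
#'
#' Binarizes a reference image of the stack, labels connected components,
#' measures each candidate (area, chain-code perimeter, circularity,
#' equivalent circular diameter), and keeps regions that (a) do not touch the
#' frame edge (when `exclude_border`), (b) exceed the minimum diameter,
#' (c) exceed the minimum circularity, and (d) are separated from every other
#' candidate by at least one background pixel. Rejected candidates are
#' recorded with the first rule they failed (`border`, `size`, `circularity`,
#' `overlap`) and the measured value.
#'
#' @param stack a calibrated [zstack()].
#' @param params a [detection_params()].
#' @return List of [grain_region] objects (possibly empty), ordered by
#'   bounding-box (row, col); the rejection log is attached as attribute
#'   `rejections` (see [rejection_log()]), the binarization threshold as
#'   attribute `threshold`.
#' @export
detect_grains <- function(stack, params = detection_params()) {
  .assert(inherits(stack, "zstack"), "stack must be a zstack")
  v <- stack$voxels
  ref <- if (params$binarization_reference == "min_projection") {
    min_projection_raw(v)
  } else {
    Reduce(`|`, lapply(seq_len(dim(v)[3]), function(s)
      binarize(v[, , s], params$binarization_method,
               fixed_threshold = params$fixed_threshold))) * 1
  }
  mask <- if (is.matrix(ref) && is.numeric(ref)) {
    binarize(ref, params$binarization_method,
             fixed_threshold = params$fixed_threshold)
  } else ref > 0
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  nlab <- max(lab)
  H <- nrow(mask); W <- ncol(mask)
  regions <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    bbox <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]) + 1L, max(idx[, 2]) + 1L)
    crop <- lab[bbox[1]:(bbox[3] - 1L), bbox[2]:(bbox[4] - 1L), drop = FALSE] == l
    regions[[l]] <- measure_region(crop, bbox, stack$pixel_size_um, id = l)
  }
  # overlap test: dilated footprint touching another candidate's footprint
  touching <- rep(FALSE, nlab)
  if (nlab > 1) {
    kern <- EBImage::makeBrush(3, "box")
    dil <- as.matrix(EBImage::imageData(
      EBImage::dilate(EBImage::Image(mask * 1), kern))) > 0
    dlab <- EBImage::bwlabel(EBImage::Image(dil * 1))
    dlab <- as.matrix(EBImage::imageData(dlab))
    # two candidates merging under 1-px dilation were < 1 background px apart
    for (dl in seq_len(max(dlab))) {
      members <- unique(lab[dlab == dl & lab > 0])
      if (length(members) > 1) touching[members] <- TRUE
    }
  }

  keep <- list(); rej <- list()
  for (r in regions) {
    on_border <- r$bbox[1] == 1L || r$bbox[2] == 1L ||
      r$bbox[3] - 1L == H || r$bbox[4] - 1L == W
    fail <- if (params$exclude_border && on_border) {
      list(rule = "border", value = NA_real_)
    } else if (r$equivalent_diameter_um <= params$diameter_min_um) {
      list(rule = "size", value = r$equivalent_diameter_um)
    } else if (r$circularity <= params$circularity_min) {
      list(rule = "circularity", value = r$circularity)
    } else if (touching[r$id]) {
      list(rule = "overlap", value = NA_real_)
    } else NULL
    if (is.null(fail)) keep[[length(keep) + 1L]] <- r
    else rej[[length(rej) + 1L]] <- data.frame(region = r$id, rule = fail$rule,
                                               value = fail$value,
                                               centre_row = r$centroid[1],
                                               centre_col = r$centroid[2])
  }
  ord <- order(vapply(keep, function(r) r$bbox[1], numeric(1)),
               vapply(keep, function(r) r$bbox[2], numeric(1)))
  keep <- keep[ord]
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(region = integer(), rule = character(), value = numeric(),
               centre_row = numeric(), centre_col = numeric())
  structure(keep, rejections = rejections,
            threshold = attr(mask, "threshold"),
            class = c("grain_detections", "list"))
}

#' @rdname detect_grains
#' @param detections result of [detect_grains()].
#' @export
rejection_log <- function(detections) attr(detections, "rejections")

#' Crop a detected grain into its own sub-stack
#'
#' The crop is the region's bounding box dilated by `margin_px` on each side,
#' clipped to the frame; all slices are retained and the calibration is
#' inherited from the parent stack.
#'
#' @param stack the parent [zstack()].
#' @param region a [grain_region] from [detect_grains()] on the same stack.
#' @param margin_px margin added around the bounding box, in pixels.
#' @return An object of class `grain_stack` with fields `voxels` (crop of
#'   all slices), `region`, `offset` (row, col of the crop origin in the
#'   parent frame), `mask` (region footprint within the crop), `margin_px`,
#'   `pixel_size_um`, `z_step_um`, `kept_slices`.
#' @export
extract_substack <- function(stack, region, margin_px = 10L) {
  .assert(inherits(stack, "zstack"), "stack must be a zstack")
  .assert(inherits(region, "grain_region"), "region must be a grain_region")
  d <- dim(stack$voxels)
  r0 <- max(1L, region$bbox[1] - margin_px)
  c0 <- max(1L, region$bbox[2] - margin_px)
  r1 <- min(d[1], region$bbox[3] - 1L + margin_px)
  c1 <- min(d[2], region$bbox[4] - 1L + margin_px)
  vox <- stack$voxels[r0:r1, c0:c1, , drop = FALSE]
  mask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
  mask[(region$bbox[1]:(region$bbox[3] - 1L)) - r0 + 1L,
       (region$bbox[2]:(region$bbox[4] - 1L)) - c0 + 1L] <- region$mask
  structure(list(voxels = vox, region = region,
                 offset = c(r0, c0), mask = mask,
                 margin_px = as.integer(margin_px),
                 pixel_size_um = stack$pixel_size_um,
                 z_step_um = stack$z_step_um,
                 kept_slices = seq_len(d[3])),
            class = "grain_stack")
}

#' @export
print.grain_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<grain_stack %s> %d x %d px, %d slice(s) kept of parent stack\n",
              x$region$id, d[1], d[2], d[3]))
  invisible(x)
}

min_projection_raw <- function(vox) {
  Reduce(pmin, lapply(seq_len(dim(vox)[3]), function(s) vox[, , s]))
}
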