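#' Calibrated Z-stack objects
#'
#' A `zstack` is a 3-D grayscale focal series: a `rows x cols x slices` array
#' of intensities in `[0, 1]` together with its physical calibration. Slice 1
#' is the first acquired focal plane; consecutive slices are `z_step_um`
#' micrometres apart; one pixel spans `pixel_size_um` micrometres.
#'
#' @param voxels numeric matrix (single slice) or `rows x cols x slices`
#'   array of finite intensities.
#' @param pixel_size_um pixel pitch in micrometres per pixel (> 0).
#' @param z_step_um focal step between consecutive slices in micrometres.
#' @param bit_depth storage bit depth used when the stack is written to disk:
#'   8 or 16.
#' @return An object of class `zstack` with fields `voxels`, `pixel_size_um`,
#'   `z_step_um`, `bit_depth`.
#' @export
zstack <- function(voxels, pixel_size_um, z_step_um = 1.8, bit_depth = 16L) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  .assert(is.array(voxels) && length(dim(voxels)) == 3L,
          "voxels must be a matrix or a rows x cols x slices array")
  .assert(all(is.finite(voxels)), "stack intensities must be finite")
  .assert(is.numeric(pixel_size_um) && length(pixel_size_um) == 1L &&
            pixel_size_um > 0, "pixel_size_um must be a single positive number")
  .assert(z_step_um > 0, "z_step_um must be positive")
  .assert(bit_depth %in% c(8L, 16L), "bit_depth must be 8 or 16")
  structure(list(voxels = voxels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 z_step_um = as.numeric(z_step_um),
                 bit_depth = as.integer(bit_depth)),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<zstack> %d x %d px, %d slice(s), %.4g um/px, dz = %.3g um, %d-bit\n",
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um, x$bit_depth))
  invisible(x)
}

#' @export
dim.zstack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3]

# quantize intensities to the grid representable at the given bit depth,
# so that a write/read cycle is bit-identical
quantize <- function(x, bit_depth) {
  mx <- 2^bit_depth - 1
  round(pmin(pmax(x, 0), 1) * mx) / mx
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write a Z-stack as a multi-page TIFF with a JSON calibration sidecar
#'
#' Intensities are quantized to the stack's `bit_depth` (this is the only
#' intensity conversion performed, and it is recorded in the sidecar); the
#' calibration (`pixel_size_um`, `z_step_um`, `bit_depth`) is written to
#' `<path>.json`, which [read_stack()] treats as the source of truth.
#'
#' @param stack a [zstack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  .assert(inherits(stack, "zstack"), "stack must be a zstack")
  v <- quantize(stack$voxels, stack$bit_depth)
  pages <- lapply(seq_len(dim(v)[3]), function(s) v[, , s])
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none", reduce = FALSE)
  write_sidecar(path, list(kind = "zstack",
                           pixel_size_um = stack$pixel_size_um,
                           z_step_um = stack$z_step_um,
                           bit_depth = stack$bit_depth))
  invisible(path)
}

#' Read a calibrated Z-stack from a multi-page TIFF
#'
#' Calibration is taken from the JSON sidecar written by [write_stack()];
#' explicit arguments override it. A stack with no sidecar and no explicit
#' `pixel_size_um` is an error, never a silent default.
#'
#' @param path TIFF path.
#' @param pixel_size_um,z_step_um calibration overrides (micrometres).
#' @return A [zstack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_step_um = NULL) {
  .assert(file.exists(path), "no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) {
      .assert(dim(p)[3] == 1L,
              "page %d of %s has %d channels; stacks must be grayscale",
              i, path, dim(p)[3])
      p <- p[, , 1L]
    }
    p
  })
  d1 <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    .assert(identical(dim(pages[[i]]), d1),
            "page %d of %s has shape %s, expected %s", i, path,
            paste(dim(pages[[i]]), collapse = "x"), paste(d1, collapse = "x"))
  }
  meta <- read_sidecar(path)
  px <- pixel_size_um %||% meta$pixel_size_um
  .assert(!is.null(px),
          "no pixel calibration for %s: missing sidecar and no pixel_size_um override",
          path)
  zstack(array(unlist(pages), dim = c(d1, length(pages))),
         pixel_size_um = px,
         z_step_um = z_step_um %||% meta$z_step_um %||% 1.8,
         bit_depth = as.integer(meta$bit_depth %||% 16L))
}

#' Fixed-frame three-channel classifier inputs
#'
#' A `framed_image` is the classifier input built by [compose_frame()]: a
#' `frame_px x frame_px x 3` array whose channels are, in order, the
#' standard-deviation, minimum-intensity and extended-depth-of-field
#' projections of one grain's focus-filtered sub-stack, placed unscaled so the
#' physical size of the grain is preserved.
#'
#' @param pixels `frame_px x frame_px x 3` numeric array in `[0, 1]`.
#' @param pixel_size_um pixel pitch in micrometres per pixel.
#' @param grain_id identifier of the source grain.
#' @param source_stack path or identifier of the parent stack.
#' @param frame_px frame side length in pixels (default 276).
#' @return An object of class `framed_image`.
#' @export
framed_image <- function(pixels, pixel_size_um, grain_id = NA_character_,
                         source_stack = NA_character_, frame_px = 276L) {
  .assert(is.array(pixels) && length(dim(pixels)) == 3L &&
            identical(as.integer(dim(pixels)), c(frame_px, frame_px, 3L)),
          "framed image must be %d x %d x 3 (got %s)", frame_px, frame_px,
          paste(dim(pixels), collapse = "x"))
  .assert(all(is.finite(pixels)), "framed image intensities must be finite")
  structure(list(pixels = pixels,
                 channels = c("stddev", "min_intensity", "extended_focus"),
                 pixel_size_um = as.numeric(pixel_size_um),
                 grain_id = as.character(grain_id),
                 source_stack = as.character(source_stack),
                 frame_px = as.integer(frame_px)),
            class = "framed_image")
}

#' @export
print.framed_image <- function(x, ...) {
  cat(sprintf("<framed_image> %d x %d x 3 (%s), %.4g um/px, grain %s\n",
              x$frame_px, x$frame_px, paste(x$channels, collapse = "/"),
              x$pixel_size_um, x$grain_id))
  invisible(x)
}

#' Write / read a framed classifier input losslessly
#'
#' Stored as an uncompressed 16-bit 3-sample TIFF plus a JSON sidecar
#' recording the channel order, calibration and provenance.
#'
#' @param image a [framed_image()].
#' @param path output TIFF path.
#' @return `path` invisibly (write); a [framed_image()] (read).
#' @export
write_framed_image <- function(image, path) {
  .assert(inherits(image, "framed_image"), "image must be a framed_image")
  tiff::writeTIFF(quantize(image$pixels, 16L), path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  write_sidecar(path, list(kind = "framed_image",
                           channels = image$channels,
                           pixel_size_um = image$pixel_size_um,
                           grain_id = image$grain_id,
                           source_stack = image$source_stack,
                           frame_px = image$frame_px))
  invisible(path)
}

#' @rdname write_framed_image
#' @export
read_framed_image <- function(path) {
  .assert(file.exists(path), "no such file: %s", path)
  px <- tiff::readTIFF(path, all = FALSE)
  .assert(length(dim(px)) == 3L && dim(px)[3] == 3L,
          "%s is not a 3-channel image", path)
  meta <- read_sidecar(path)
  .assert(!is.null(meta) && !is.null(meta$pixel_size_um),
          "no calibration sidecar for %s", path)
  img <- framed_image(px, pixel_size_um = meta$pixel_size_um,
                      grain_id = meta$grain_id %||% NA_character_,
                      source_stack = meta$source_stack %||% NA_character_,
                      frame_px = as.integer(dim(px)[1]))
  .assert(identical(unlist(meta$channels), img$channels),
          "unexpected channel order in %s sidecar", path)
  img
}

#' Dataset manifests
#'
#' A manifest lists one stack (or framed image) per row with its class label
#' and the identifier of the plant or aerobiological sample it came from, so
#' cross-validation can group images that share a source.
#'
#' @param df data frame with columns `path`, `label`, `sample_id`.
#' @param path CSV path.
#' @param labels optional declared label set; `label` values must be drawn
#'   from it or be `"unlabelled"`.
#' @return The validated manifest data frame.
#' @export
write_manifest <- function(df, path) {
  df <- validate_manifest(df)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, labels = NULL) {
  .assert(file.exists(path), "no such file: %s", path)
  validate_manifest(read.csv(path, stringsAsFactors = FALSE), labels = labels)
}

validate_manifest <- function(df, labels = NULL) {
  .assert(all(c("path", "label", "sample_id") %in% names(df)),
          "manifest needs columns path, label, sample_id")
  .assert(!anyDuplicated(df$path), "manifest paths must be unique")
  if (!is.null(labels)) {
    bad <- setdiff(unique(df$label), c(labels, "unlabelled"))
    .assert(length(bad) == 0L, "manifest labels outside declared set: %s",
            paste(bad, collapse = ", "))
  }
  df
}
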