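#' DaTscan-style volume container
#'
#' Wraps a 3-D intensity array ordered (slice, row, column). PPMI-style
#' DaTscan SPECT reconstructions come as 91 slices of 109 x 91 voxels; any
#' positive axis sizes are accepted.
#'
#' @param voxels 3-D numeric array, finite and nonnegative, dims
#'   (n_slices, height, width).
#' @param source free-text provenance identifier.
#' @return object of class `datscan_volume`.
#' @export
datscan_volume <- function(voxels, source = "in-memory") {
  voxels <- unclass(voxels)
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L)) {
    stop_data("voxels must be a 3-D array with positive axis sizes")
  }
  if (any(!is.finite(voxels)) || any(voxels < 0)) {
    stop_data("voxel intensities must be finite and nonnegative")
  }
  structure(list(voxels = voxels, source = source), class = "datscan_volume")
}

#' @export
print.datscan_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<datscan_volume: %d slices of %d x %d, source: %s>\n",
              d[1L], d[2L], d[3L], x$source))
  invisible(x)
}

#' Read a volume from file
#'
#' Reads a NIfTI volume (via the RNifti package) into a [datscan_volume()].
#' NIfTI stores axes (x, y, z); they are reordered so the third axis becomes
#' the leading slice axis.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return a `datscan_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_data("volume file not found: ", path)
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop_usage("reading NIfTI volumes requires the RNifti package")
  }
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 3L) stop_data("expected a 3-D volume in ", path)
  datscan_volume(aperm(a, c(3L, 2L, 1L)), source = path)
}

#' 2-D slice with provenance
#'
#' @param pixels 2-D numeric matrix of intensities.
#' @param slice_index 1-based index of the slice in its source volume
#'   (`NA` when unknown).
#' @param crop_box integer vector `(top, left, bottom, right)` in 0-based
#'   half-open pixel coordinates of the most recent crop, or `NULL`.
#' @param source provenance string.
#' @return object of class `slice_image`.
#' @export
slice_image <- function(pixels, slice_index = NA_integer_, crop_box = NULL,
                        source = "in-memory") {
  pixels <- as.matrix(pixels)
  if (!length(pixels)) stop_data("empty image")
  if (any(!is.finite(pixels))) stop_data("pixel intensities must be finite")
  structure(list(pixels = pixels, slice_index = as.integer(slice_index),
                 crop_box = crop_box, source = source),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image: %d x %d, slice %s, range [%g, %g]>\n",
              nrow(x$pixels), ncol(x$pixels),
              ifelse(is.na(x$slice_index), "?", x$slice_index),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Extract one axial slice from a volume
#'
#' The DaTscan pipeline works on a single informative slice per volume; for
#' 91-slice PPMI-style reconstructions the mid-striatal slice 41 (1-based) is
#' the conventional choice and the default here.
#'
#' @param vol a [datscan_volume()].
#' @param index 1-based slice index (default 41).
#' @return a [slice_image()] of shape (height, width).
#' @export
extract_slice <- function(vol, index = 41L) {
  stopifnot(inherits(vol, "datscan_volume"))
  index <- as.integer(index)
  n <- dim(vol$voxels)[1L]
  if (is.na(index) || index < 1L || index > n) {
    stop_data("slice index ", index, " out of range 1..", n)
  }
  slice_image(vol$voxels[index, , ], slice_index = index, source = vol$source)
}

#' Crop the black border of a slice
#'
#' Tight bounding box of pixels strictly above `threshold`; the surrounding
#' black margin (scanner background) is discarded. Because brain extent
#' varies between subjects, the resulting sizes are irregular — resize
#' afterwards with [resize_and_scale()]. An image that is entirely at or
#' below the threshold has no content to bound; by convention it collapses to
#' its 1 x 1 centre pixel. Idempotent: cropping an already-cropped image is
#' the identity.
#'
#' @param img a [slice_image()].
#' @param threshold intensities strictly greater count as content (default 0,
#'   i.e. strictly black borders).
#' @return cropped [slice_image()] with `crop_box` set to
#'   `(top, left, bottom, right)` in 0-based half-open coordinates.
#' @export
crop_black_border <- function(img, threshold = 0) {
  stopifnot(inherits(img, "slice_image"))
  px <- img$pixels
  keep_r <- which(apply(px > threshold, 1, any))
  keep_c <- which(apply(px > threshold, 2, any))
  if (!length(keep_r)) {
    r <- (nrow(px) + 1L) %/% 2L
    c <- (ncol(px) + 1L) %/% 2L
    box <- c(top = r - 1L, left = c - 1L, bottom = r, right = c)
    return(slice_image(px[r, c, drop = FALSE], img$slice_index, box,
                       img$source))
  }
  r0 <- min(keep_r); r1 <- max(keep_r)
  c0 <- min(keep_c); c1 <- max(keep_c)
  box <- c(top = r0 - 1L, left = c0 - 1L, bottom = r1, right = c1)
  slice_image(px[r0:r1, c0:c1, drop = FALSE], img$slice_index, box,
              img$source)
}

#' Resize to a square and min-max scale to \[0, 1\]
#'
#' Bilinear resize to `side` x `side` (the 224 default matches the input
#' resolution of standard ImageNet-style CNNs), then linear rescale so the
#' minimum maps to 0 and the maximum to 1. A constant image carries no
#' contrast and maps to all zeros.
#'
#' @param img a [slice_image()].
#' @param side output side length in pixels (default 224).
#' @return a [slice_image()] of shape `side` x `side` with values in \[0, 1\].
#' @export
resize_and_scale <- function(img, side = 224L) {
  stopifnot(inherits(img, "slice_image"))
  side <- as.integer(side)
  if (is.na(side) || side < 1L) stop_usage("side must be a positive integer")
  px <- EBImage::imageData(
    EBImage::resize(EBImage::Image(img$pixels), w = side, h = side,
                    filter = "bilinear"))
  rng <- range(px)
  px <- if (rng[2L] > rng[1L]) (px - rng[1L]) / (rng[2L] - rng[1L])
        else array(0, dim(px))
  slice_image(matrix(px, side, side), img$slice_index, img$crop_box,
              img$source)
}

#' Brightness augmentation
#'
#' Multiplies intensities by a brightness factor and clips to \[0, 1\] — the
#' standard training-time augmentation with factors spanning darkening (< 1)
#' and brightening (> 1). Never applied at evaluation time. If `factor` is
#' omitted it is drawn uniformly from `range` (seed it for reproducibility).
#'
#' @param img a [slice_image()] with values in \[0, 1\].
#' @param factor brightness multiplier; must lie inside `range`.
#' @param range allowed factor interval, default `c(0.1, 1.5)`.
#' @param seed optional integer seeding the draw when `factor` is omitted.
#' @return the adjusted [slice_image()].
#' @export
brightness_augment <- function(img, factor = NULL, range = c(0.1, 1.5),
                               seed = NULL) {
  stopifnot(inherits(img, "slice_image"))
  if (is.null(factor)) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    factor <- stats::runif(1L, range[1L], range[2L])
  }
  if (!is.numeric(factor) || length(factor) != 1L ||
      factor < range[1L] || factor > range[2L]) {
    stop_usage(sprintf("brightness factor must lie in [%g, %g]",
                       range[1L], range[2L]))
  }
  px <- pmin(pmax(img$pixels * factor, 0), 1)
  slice_image(px, img$slice_index, img$crop_box, img$source)
}

#' Full single-slice preprocessing pipeline
#'
#' Convenience composition `extract_slice() |> crop_black_border() |>
#' resize_and_scale()`: from a raw volume to a square, contrast-normalized
#' slice ready for a CNN-style consumer.
#'
#' @inheritParams extract_slice
#' @inheritParams crop_black_border
#' @inheritParams resize_and_scale
#' @return a [slice_image()], `side` x `side` in \[0, 1\].
#' @export
preprocess_volume <- function(vol, index = 41L, threshold = 0, side = 224L) {
  resize_and_scale(crop_black_border(extract_slice(vol, index), threshold),
                   side)
}

#' Write / read a slice image
#'
#' `write_slice()` writes PNG (8-bit grayscale) or, for lossless 16-bit
#' output, TIFF — chosen by the file extension. `read_slice()` reads either
#' back. Values must already lie in \[0, 1\].
#'
#' @param img a [slice_image()] with values in \[0, 1\].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `write_slice()`: the path, invisibly. `read_slice()`: a
#'   [slice_image()].
#' @export
write_slice <- function(img, path) {
  stopifnot(inherits(img, "slice_image"))
  px <- img$pixels
  if (min(px) < 0 || max(px) > 1) {
    stop_data("slice values must be in [0, 1] before export; run resize_and_scale()")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 16L)
  } else {
    stop_usage("unsupported image extension: .", ext)
  }
  invisible(path)
}

#' @rdname write_slice
#' @export
read_slice <- function(path) {
  if (!file.exists(path)) stop_data("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") png::readPNG(path)
        else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
        else stop_usage("unsupported image extension: .", ext)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # drop colour channels
  slice_image(px, source = path)
}

#' Random train/test split
#'
#' Seeded random partition of labelled sample ids into train and test sets
#' with `round(test_fraction * n)` test samples. Non-stratified by default
#' (a plain random draw, so class proportions in the test set fluctuate);
#' set `stratified = TRUE` to split each class separately.
#'
#' @param sample_ids vector of unique sample identifiers.
#' @param labels vector of class labels, same length.
#' @param test_fraction fraction held out, strictly between 0 and 1
#'   (default 0.2 — the usual 80:20 split).
#' @param seed optional integer seed for the shuffle.
#' @param stratified logical; split within each class.
#' @return list with data.frames `train` and `test`, each with columns
#'   `sample_id`, `label`.
#' @examples
#' split_dataset(1:10, rep(c("PD", "HC"), 5), seed = 1)
#' @export
split_dataset <- function(sample_ids, labels, test_fraction = 0.2,
                          seed = NULL, stratified = FALSE) {
  n <- length(sample_ids)
  if (n < 2L) stop_data("need at least two samples to split")
  if (length(labels) != n) stop_data("sample_ids and labels lengths differ")
  if (anyDuplicated(sample_ids)) stop_data("sample_ids must be unique")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop_usage("test_fraction must lie strictly between 0 and 1")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  df <- data.frame(sample_id = sample_ids, label = labels,
                   stringsAsFactors = FALSE)
  if (stratified) {
    test_idx <- unlist(lapply(split(seq_len(n), labels), function(idx) {
      sample(idx, round(test_fraction * length(idx)))
    }), use.names = FALSE)
  } else {
    test_idx <- sample(n, round(test_fraction * n))
  }
  list(train = df[-test_idx, , drop = FALSE],
       test = df[test_idx, , drop = FALSE])
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
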