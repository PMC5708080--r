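#' @title Datasets and axes
#' @description
#' A dataset wraps an image by reference together with named calibrated axes
#' (preset types X, Y, Z, TIME, CHANNEL or custom labels, each with a unit
#' and a physical scale per sample), a name, and optional per-channel LUT
#' name references.  Wrapping is by reference: the dataset and the image
#' share samples, so edits through either are visible through both.
#' @name datasets
NULL

.axis_presets <- c("X", "Y", "Z", "TIME", "CHANNEL")

#' Construct a calibrated axis
#'
#' @param axis_type one of the presets `X`, `Y`, `Z`, `TIME`, `CHANNEL`, or a
#'   custom label
#' @param unit unit string (e.g. `"um"`); empty = uncalibrated
#' @param scale physical units per sample; must be > 0
#' @return an `nd_axis`
#' @export
axis <- function(axis_type, unit = "", scale = 1) {
  stopifnot(is.character(axis_type), length(axis_type) == 1L, nzchar(axis_type))
  if (!is.numeric(scale) || length(scale) != 1L || !(scale > 0))
    stop("axis scale must be > 0")
  structure(list(axis_type = axis_type, unit = unit, scale = as.numeric(scale)),
            class = "nd_axis")
}

is_dataset <- function(x) inherits(x, "nd_dataset")

default_axes <- function(ndim) {
  labels <- c(.axis_presets, paste0("DIM", seq_len(max(0L, ndim - 5L)) + 5L))
  lapply(labels[seq_len(ndim)], axis)
}

#' Wrap an image into a dataset
#'
#' @param img an `ndimg`
#' @param axes list of [axis()] objects, one per dimension
#' @param name dataset name
#' @param channel_luts optional character vector of LUT names; when a CHANNEL
#'   axis is present its length must equal the channel extent
#' @return an `nd_dataset` sharing the image by reference
#' @export
wrap_dataset <- function(img, axes = default_axes(img$ndim), name = "",
                         channel_luts = NULL) {
  stopifnot(is_ndimg(img))
  if (length(axes) != img$ndim)
    stop("metadata error: ", length(axes), " axes for a ", img$ndim,
         "-dimensional image")
  for (a in axes) stopifnot(inherits(a, "nd_axis"))
  types <- vapply(axes, function(a) a$axis_type, character(1))
  if (!is.null(channel_luts)) {
    ch <- which(types == "CHANNEL")
    if (length(ch) == 1L && length(channel_luts) != img$shape[[ch]])
      stop("metadata error: ", length(channel_luts), " LUTs for ",
           fmt_extent(img$shape[[ch]]), " channels")
  }
  ds <- new.env(parent = emptyenv())
  class(ds) <- "nd_dataset"
  ds$image <- img
  ds$axes <- axes
  ds$name <- name
  ds$channel_luts <- channel_luts
  ds
}

#' @export
print.nd_dataset <- function(x, ...) {
  cat("<dataset '", x$name, "' ", x$image$type$name, " [",
      paste(x$image$shape_chr, collapse = "x"), "] axes: ",
      paste(vapply(x$axes, function(a) a$axis_type, character(1)),
            collapse = ","), ">\n", sep = "")
  invisible(x)
}

#' Dataset accessors
#'
#' @param ds an `nd_dataset`
#' @return `dataset_image()` the wrapped image (by reference);
#'   `dataset_axes()` the axis list; `physical_extent()` the per-dimension
#'   extent in physical units (`shape * scale`).
#' @export
dataset_image <- function(ds) ds$image

#' @rdname dataset_image
#' @export
dataset_axes <- function(ds) ds$axes

#' @rdname dataset_image
#' @export
physical_extent <- function(ds) {
  ds$image$shape * vapply(ds$axes, function(a) a$scale, numeric(1))
}

# image from an image-or-dataset argument
as_image <- function(x) {
  if (is_ndimg(x)) x
  else if (is_dataset(x)) x$image
  else stop("expected an image or dataset, got ", type_of(x))
}
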