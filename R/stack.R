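#' Multichannel image stack
#'
#' A `channel_stack` holds one registered grayscale plane per named channel,
#' an optional region-of-interest (ROI) mask, and the pixel size. All planes
#' (and the ROI, if present) must share one shape and channel names must be
#' unique. The ROI defaults to the whole frame. Pixel convention: a pixel is
#' one unit of area; areas are pixel counts, convertible to nm^2 when
#' `pixel_size` is known.
#'
#' @param channels named list of numeric matrices, one per channel.
#' @param roi logical (or 0/1 numeric) matrix of the same shape, `TRUE`/nonzero
#'   inside the ROI, or `NULL` for the whole frame.
#' @param pixel_size nm per pixel, or `NA` if unknown.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, roi = NULL, pixel_size = NA_real_) {
  if (!is.list(channels) || length(channels) < 1 ||
      is.null(names(channels)) || anyDuplicated(names(channels)) ||
      any(!nzchar(names(channels))))
    abort("`channels` must be a named list with unique non-empty names",
          class = "venncf_parameter_error")
  shp <- dim(channels[[1]])
  for (nm in names(channels)) {
    p <- channels[[nm]]
    if (!is.matrix(p) || !is.numeric(p))
      abort(sprintf("channel '%s' is not a numeric matrix", nm),
            class = "venncf_parameter_error")
    if (!identical(dim(p), shp))
      abort(sprintf("channel '%s' has shape %s, expected %s", nm,
                    paste(dim(p), collapse = "x"),
                    paste(shp, collapse = "x")),
            class = "venncf_shape_error")
  }
  if (!is.null(roi)) {
    if (!identical(dim(roi), shp))
      abort(sprintf("ROI has shape %s, expected %s",
                    paste(dim(roi), collapse = "x"),
                    paste(shp, collapse = "x")),
            class = "venncf_shape_error")
    roi <- matrix(as.logical(roi != 0), shp[1], shp[2])
  }
  structure(list(channels = channels, roi = roi, pixel_size = pixel_size),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  shp <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack> %dx%d px, %d channel(s): %s\n", shp[1], shp[2],
              length(x$channels), paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel size: %s; ROI: %s\n",
              if (is.na(x$pixel_size)) "unknown"
              else paste0(x$pixel_size, " nm/px"),
              if (is.null(x$roi)) "whole frame"
              else paste0(sum(x$roi), " px")))
  invisible(x)
}

roi_or_full <- function(stack) {
  if (!is.null(stack$roi)) return(stack$roi)
  shp <- dim(stack$channels[[1]])
  matrix(TRUE, shp[1], shp[2])
}

read_mask_file <- function(path) {
  if (!file.exists(path))
    abort(sprintf("mask file not found: %s", path), class = "venncf_io_error")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img != 0
}

#' Load a multichannel TIFF into a channel stack
#'
#' Reads a multi-page TIFF (one grayscale page per channel) and maps pages to
#' `channel_names` in order. An optional ROI mask (TIFF or PNG; nonzero =
#' inside) restricts all downstream area computations.
#'
#' @param path TIFF file with at least `length(channel_names)` pages.
#' @param channel_names character vector naming the planes in page order.
#' @param roi_path optional path to an ROI mask of the same shape.
#' @param pixel_size nm/pixel if known (TIFF resolution metadata is not
#'   relied upon).
#' @return A [channel_stack()].
#' @export
load_stack <- function(path, channel_names, roi_path = NULL,
                       pixel_size = NA_real_) {
  if (!file.exists(path))
    abort(sprintf("image file not found: %s", path),
          class = "venncf_io_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < length(channel_names))
    abort(sprintf(
      "%s: expected >= %d grayscale pages for channels %s, found %d", path,
      length(channel_names), paste(channel_names, collapse = ", "),
      length(pages)), class = "venncf_io_error")
  pages <- pages[seq_along(channel_names)]
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) != 2)
      abort(sprintf("%s: page %d is not a single grayscale plane", path, i),
            class = "venncf_io_error")
  }
  names(pages) <- channel_names
  roi <- if (!is.null(roi_path)) read_mask_file(roi_path) else NULL
  channel_stack(pages, roi = roi, pixel_size = pixel_size)
}

#' Write a channel stack as a multi-page 32-bit TIFF
#'
#' One 32-bit page per channel, in channel order; intensities round-trip
#' through [load_stack()] to within 2^-32 per pixel. Channel names are not
#' stored in the TIFF; keep them in a sidecar (see [write_ground_truth()])
#' or supply them to [load_stack()] at read time.
#'
#' @param stack a [channel_stack()]; plane values must lie in \[0, 1\]
#'   (simulated stacks already do).
#' @param path output TIFF path.
#' @param roi_path optional path to also write the ROI as a single-page TIFF.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, roi_path = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  tiff::writeTIFF(unname(stack$channels), path, bits.per.sample = 32L)
  if (!is.null(roi_path) && !is.null(stack$roi))
    tiff::writeTIFF(matrix(as.numeric(stack$roi), nrow(stack$roi)),
                    roi_path, bits.per.sample = 8L)
  invisible(path)
}
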