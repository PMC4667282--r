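#' Frame stacks
#'
#' A `frame_stack` is an ordered grid of per-frame pixel intensities — the
#' in-memory surrogate of a thermal-imaging video. Intensities are raw,
#' temperature-linear counts (no radiometric calibration is attempted).
#'
#' @param frames numeric array of dimension `T x H x W`, non-negative finite
#'   intensities; at least two frames.
#' @param frame_rate_hz frames per second (default 9, the acquisition rate of
#'   the thermal camera setup the defaults emulate).
#' @param source_id free-text provenance label.
#' @return An object of class `frame_stack` with fields `frames`,
#'   `frame_rate_hz` and `source_id`.
#' @seealso [load_frame_stack()], [crop_roi()], [mean_series()]
#' @export
frame_stack <- function(frames, frame_rate_hz = 9, source_id = "") {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    tn_stop("thermonet_format_error", "frames must be a T x H x W array")
  d <- dim(frames)
  if (d[1] < 2L)
    tn_stop("thermonet_insufficient_data", "need at least 2 frames, got %d", d[1])
  if (d[2] < 1L || d[3] < 1L)
    tn_stop("thermonet_format_error", "frame height and width must be >= 1")
  if (!all(is.finite(frames)) || any(frames < 0))
    tn_stop("thermonet_format_error", "intensities must be finite and non-negative")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L || frame_rate_hz <= 0)
    tn_stop("thermonet_parameter_error", "frame_rate_hz must be a positive scalar")
  structure(
    list(frames = frames, frame_rate_hz = as.numeric(frame_rate_hz),
         source_id = as.character(source_id)),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %d x %d px @ %g Hz%s\n",
              d[1], d[2], d[3], x$frame_rate_hz,
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

#' Rectangular region-of-interest specification
#'
#' Pixel coordinates are 1-based; the ROI covers rows `y0 .. y0+height-1`
#' and columns `x0 .. x0+width-1`.
#'
#' @param x0,y0 1-based column/row of the top-left pixel.
#' @param width,height extent in pixels, both `>= 1`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x0, y0, width, height) {
  v <- c(x0 = x0, y0 = y0, width = width, height = height)
  if (any(v != round(v)) || x0 < 1 || y0 < 1 || width < 1 || height < 1)
    tn_stop("thermonet_parameter_error", "roi fields must be integers with x0,y0 >= 1 and width,height >= 1")
  structure(stats::setNames(as.list(as.integer(v)), names(v)), class = "roi_spec")
}

#' Load a frame stack from disk
#'
#' Accepts either a multi-page TIFF file or a directory of equally sized
#' single-frame TIFF/PNG images; directory frames are ordered by
#' lexicographic filename order. TIFF pixels are read as raw integer counts;
#' PNG pixels (decoded to \[0,1\]) are rescaled to 16-bit counts. Multi-channel
#' images are averaged over channels.
#'
#' @param path multi-page TIFF file, or directory of single-frame images.
#' @param frame_rate_hz frames per second recorded as metadata (default 9).
#' @param source_id provenance label; defaults to `path`.
#' @return A [frame_stack()].
#' @export
load_frame_stack <- function(path, frame_rate_hz = 9, source_id = path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
    files <- file.path(path, sort(files))
    if (length(files) < 2L)
      tn_stop("thermonet_insufficient_data", "directory holds %d frame image(s); need >= 2", length(files))
    pages <- lapply(files, read_frame_image)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      tn_stop("thermonet_insufficient_data", "TIFF holds %d page(s); need >= 2", length(pages))
    pages <- lapply(pages, flatten_channels)
  } else {
    tn_stop("thermonet_parameter_error", "path does not exist: %s", path)
  }
  shp <- vapply(pages, function(p) paste(dim(p), collapse = "x"), character(1))
  if (length(unique(shp)) != 1L)
    tn_stop("thermonet_format_error", "frames differ in shape: %s",
            paste(unique(shp), collapse = ", "))
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  frame_stack(arr, frame_rate_hz = frame_rate_hz, source_id = source_id)
}

# read one single-frame image file as a numeric intensity matrix
read_frame_image <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- switch(ext,
    png = png::readPNG(file) * 65535,
    tif = ,
    tiff = {
      p <- tiff::readTIFF(file, all = TRUE, as.is = TRUE)
      if (is.list(p)) p[[1]] else p
    },
    tn_stop("thermonet_format_error", "unsupported frame format: %s", file)
  )
  flatten_channels(img)
}

# average channel dimension away if present
flatten_channels <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  storage.mode(img) <- "double"
  img
}

#' Write a frame stack to a multi-page 16-bit TIFF
#'
#' Intensities must lie in `[0, 65535]` and are rounded to integer counts, so
#' integer-valued stacks round-trip bit-identically through
#' [load_frame_stack()].
#'
#' @param stack a [frame_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  if (any(stack$frames < 0) || any(stack$frames > 65535))
    tn_stop("thermonet_format_error", "16-bit TIFF output requires intensities in [0, 65535]")
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(t) round(stack$frames[t, , ]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Crop a frame stack to a region of interest
#'
#' @param stack a [frame_stack()].
#' @param roi a [roi_spec()]; must lie entirely inside the frame.
#' @return A new [frame_stack()] of the same length with `H = height`,
#'   `W = width`; pixel data are copied, never aliased.
#' @export
crop_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "frame_stack"), inherits(roi, "roi_spec"))
  d <- dim(stack$frames)
  rows <- roi$y0:(roi$y0 + roi$height - 1L)
  cols <- roi$x0:(roi$x0 + roi$width - 1L)
  if (max(rows) > d[2] || max(cols) > d[3])
    tn_stop("thermonet_bounds_error",
            "ROI (%d:%d, %d:%d) exceeds frame extent %d x %d",
            min(rows), max(rows), min(cols), max(cols), d[2], d[3])
  frame_stack(stack$frames[, rows, cols, drop = FALSE],
              frame_rate_hz = stack$frame_rate_hz,
              source_id = stack$source_id)
}
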