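#' Construct a video stack
#'
#' A `VideoStack` is the raw substrate of both assays: an ordered set of
#' grayscale frames with acquisition metadata. High-speed ciliary videos are
#' typically acquired at ~1000 frames/s; bead time-lapse movies at 5 frames/s
#' (one frame every 200 ms).
#'
#' @param frames numeric 3-D array, time x rows x cols, intensities in [0,1].
#' @param frame_rate_hz frames per second; must be positive.
#' @param pixel_size_um micrometres per pixel (isotropic); must be positive.
#' @param origin_path provenance string (file the stack came from, or a
#'   simulator tag).
#' @return an object of class `VideoStack`.
#' @export
video_stack <- function(frames, frame_rate_hz, pixel_size_um = NA_real_,
                        origin_path = NA_character_) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_ciliaflow("frames must be a 3-D array (time x rows x cols)")
  if (dim(frames)[1] < 2L)
    stop_ciliaflow("a video stack needs at least 2 frames")
  if (!all(is.finite(frames)))
    stop_ciliaflow("frame intensities must be finite")
  if (min(frames) < 0 || max(frames) > 1)
    stop_ciliaflow("frame intensities must lie in [0,1] after normalization")
  if (!is_scalar_num(frame_rate_hz, lo = 0))
    stop_ciliaflow("frame_rate_hz must be a single positive number")
  if (!is.na(pixel_size_um) && !is_scalar_num(pixel_size_um, lo = 0))
    stop_ciliaflow("pixel_size_um must be a single positive number")
  structure(
    list(frames = frames,
         frame_rate_hz = as.numeric(frame_rate_hz),
         pixel_size_um = as.numeric(pixel_size_um),
         origin_path = as.character(origin_path)),
    class = "VideoStack")
}

#' @export
print.VideoStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("VideoStack: %d frames of %d x %d px, %.6g fps, %s um/px\n",
              d[1], d[2], d[3], x$frame_rate_hz,
              format(x$pixel_size_um)))
  invisible(x)
}

#' @export
dim.VideoStack <- function(x) dim(x$frames)

#' Construct a layer mask
#'
#' A binary mask restricting ROI placement to the ependymal layer of a video.
#'
#' @param mask logical matrix, same rows/cols as the frames of the stack the
#'   mask belongs to.
#' @param label free-text label (default "ependymal layer").
#' @return an object of class `LayerMask`.
#' @export
layer_mask <- function(mask, label = "ependymal layer") {
  if (!is.matrix(mask)) stop_ciliaflow("mask must be a matrix")
  if (!is.logical(mask)) {
    storage.mode(mask) <- "double"
    mask <- mask != 0
  }
  if (anyNA(mask)) stop_ciliaflow("mask may not contain NA")
  structure(list(mask = mask, label = as.character(label)),
            class = "LayerMask")
}

#' @export
print.LayerMask <- function(x, ...) {
  cat(sprintf("LayerMask '%s': %d x %d px, %d inside\n", x$label,
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

# Reduce a readTIFF page (matrix or rows x cols x channels array) to a
# grayscale matrix by channel mean.
page_to_gray <- function(page) {
  if (is.matrix(page)) return(page)
  if (is.array(page) && length(dim(page)) == 3L)
    return(rowMeans(page, dims = 2L))
  stop_ciliaflow("unsupported TIFF page layout")
}

read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, page_to_gray)
}

#' Read an image stack from disk
#'
#' Reads a multi-page grayscale TIFF (or a directory of same-shaped
#' single-page TIFFs, in lexicographic filename order) into a [video_stack()].
#' 8/16-bit integer data are scaled by the type maximum, so intensities are
#' floating values in [0,1]. Metadata precedence is: explicit argument >
#' JSON sidecar (`<path>.json` with keys `frame_rate_hz`, `pixel_size_um`).
#' A missing frame rate is an error, because every downstream frequency
#' depends on it.
#'
#' @param path TIFF file or directory of TIFF files.
#' @param frame_rate_hz optional frame-rate override (Hz).
#' @param pixel_size_um optional pixel-size override (micrometres/pixel).
#' @return a `VideoStack`.
#' @export
read_stack <- function(path, frame_rate_hz = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop_ciliaflow("cannot read '", path, "'")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) < 2L)
      stop_ciliaflow("directory must contain at least 2 TIFF frames")
    pages <- unlist(lapply(files, read_tiff_pages), recursive = FALSE)
  } else {
    pages <- read_tiff_pages(path)
  }
  if (length(pages) < 2L)
    stop_ciliaflow("single-frame input: a video stack needs >= 2 frames")
  shp <- dim(pages[[1]])
  same <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
  if (!all(same)) stop_ciliaflow("inconsistent frame shape across pages")

  meta <- list(frame_rate_hz = NULL, pixel_size_um = NULL)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    got <- jsonlite::read_json(sc, simplifyVector = TRUE)
    meta$frame_rate_hz <- got$frame_rate_hz
    meta$pixel_size_um <- got$pixel_size_um
  }
  fr <- if (!is.null(frame_rate_hz)) frame_rate_hz else meta$frame_rate_hz
  px <- if (!is.null(pixel_size_um)) pixel_size_um else meta$pixel_size_um
  if (is.null(fr) || !is_scalar_num(fr, lo = 0))
    stop_ciliaflow("frame rate missing or non-positive: pass frame_rate_hz ",
                   "or provide a JSON sidecar")
  if (is.null(px)) px <- NA_real_

  frames <- array(0, dim = c(length(pages), shp))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  video_stack(frames, fr, px, origin_path = normalizePath(path))
}

#' Write an image stack to disk
#'
#' Writes a multi-page 16-bit grayscale TIFF plus a JSON sidecar
#' (`<path>.json`) carrying `frame_rate_hz` and `pixel_size_um`. Round
#' trips through [read_stack()] preserve shape and metadata exactly and
#' intensities to 16-bit quantization (<= 1/65535 per pixel).
#'
#' @param stack a `VideoStack`.
#' @param path destination TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "VideoStack"))
  pages <- lapply(seq_len(dim(stack$frames)[1]),
                  function(t) stack$frames[t, , ])
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop_ciliaflow("cannot write '", path, "'")
  jsonlite::write_json(
    list(frame_rate_hz = stack$frame_rate_hz,
         pixel_size_um = stack$pixel_size_um),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a layer mask from a single-page image
#'
#' Nonzero pixels mean "inside layer". The mask must match the frame shape
#' of the stack it will be used with; an all-false mask is allowed here (with
#' a warning) and only fails at ROI-sampling time.
#'
#' @param path single-page TIFF path.
#' @param expected_shape integer c(rows, cols) the mask must match.
#' @param label mask label.
#' @return a `LayerMask`.
#' @export
read_mask <- function(path, expected_shape, label = "ependymal layer") {
  pages <- read_tiff_pages(path)
  if (length(pages) != 1L)
    stop_ciliaflow("mask must be a single-page image")
  m <- pages[[1]]
  if (!identical(dim(m), as.integer(expected_shape)))
    stop_ciliaflow("mask shape (", nrow(m), " x ", ncol(m),
                   ") does not match expected (",
                   expected_shape[1], " x ", expected_shape[2], ")")
  if (!any(m != 0)) warning("mask has no nonzero pixels")
  layer_mask(m != 0, label = label)
}

#' Write a layer mask as an 8-bit TIFF
#'
#' @param mask a `LayerMask`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "LayerMask"))
  tiff::writeTIFF(mask$mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
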