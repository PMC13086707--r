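## Per-frame reflected-light extraction: integrated density over a circular
## ROI, the standard ImageJ-style measure (ROI area x mean grey value).

# Logical membership mask of a circular ROI in a frame of given dim.
# Pixel-centre convention: pixel (row r, col c), 1-based in R, has centre
# (x = c - 1, y = r - 1).
.roiMask <- function(roi, dims) {
  xs <- matrix(rep(0:(dims[2] - 1), each = dims[1]), dims[1])
  ys <- matrix(rep(0:(dims[1] - 1), times = dims[2]), dims[1])
  (xs - roi@cx)^2 + (ys - roi@cy)^2 <= roi@radius^2
}

.checkRoiInside <- function(roi, dims) {
  ok <- roi@cx - roi@radius >= 0 && roi@cy - roi@radius >= 0 &&
    roi@cx + roi@radius <= dims[2] - 1 &&
    roi@cy + roi@radius <= dims[1] - 1
  if (!ok)
    stop(sprintf(paste0(
      "ROI (centre %.4g, %.4g, radius %.4g) extends outside the ",
      "%d x %d px frame (valid centre range: x in [%g, %g], ",
      "y in [%g, %g])"),
      roi@cx, roi@cy, roi@radius, dims[1], dims[2],
      roi@radius, dims[2] - 1 - roi@radius,
      roi@radius, dims[1] - 1 - roi@radius))
  invisible(TRUE)
}

#' Integrated density over a circular ROI
#'
#' The per-frame reflected-light measure: ROI area times the mean grey
#' value of the member pixels, which equals the plain sum of member-pixel
#' grey values when the area is taken as the member-pixel count (as here).
#' A pixel is a member when its centre lies within the ROI radius.
#'
#' @param frame a numeric matrix of grey values.
#' @param roi a \linkS4class{CircularROI}, fully inside the frame.
#' @return A single nonnegative number (grey times px^2).
#' @export
#' @examples
#' f <- matrix(7, 32, 32)
#' integratedDensity(f, CircularROI(15.5, 15.5, 5))
integratedDensity <- function(frame, roi) {
  stopifnot(is.matrix(frame), is(roi, "CircularROI"))
  .checkRoiInside(roi, dim(frame))
  sum(frame[.roiMask(roi, dim(frame))])
}

#' @rdname extractSeries
#' @aliases extractSeries,FrameStack,CircularROI-method
#' @param meanGrey when TRUE, divide by the ROI pixel count so values are
#'   mean grey instead of integrated density.
setMethod("extractSeries", signature("FrameStack", "CircularROI"),
          function(stack, roi, meanGrey = FALSE) {
  if (length(stack) == 0L) stop("empty frame stack")
  dims <- dim(stack@frames)[1:2]
  .checkRoiInside(roi, dims)
  mask <- .roiMask(roi, dims)
  vals <- vapply(seq_len(length(stack)),
                 function(i) sum(stack@frames[, , i][mask]), numeric(1))
  if (meanGrey) vals <- vals / sum(mask)
  ReflectanceSeries(times = stack@timestamps, values = vals, units = "raw")
})

#' Read a frame stack from disk
#'
#' Reads either a multi-page grayscale TIFF or a directory of PNG frames
#' (sorted by file name). Timestamps come from a sidecar CSV with a
#' \code{time_s} column (default \code{<path>_timestamps.csv} next to the
#' stack), or from the \code{timestamps} argument; without either, frames
#' are numbered 0, 1, 2, ... seconds.
#'
#' @param path TIFF file or PNG directory.
#' @param timestamps optional numeric vector of frame times, seconds.
#' @param bitDepth assumed bit depth used to rescale intensities read on a
#'   0..1 scale (default 8).
#' @return A \linkS4class{FrameStack}.
#' @export
readFrameStack <- function(path, timestamps = NULL, bitDepth = 8L) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no PNG frames found in ", path)
    frames <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]  # grayscale channel
      round(m * (2^bitDepth - 1))
    })
  } else {
    if (!file.exists(path)) stop("no such file or directory: ", path)
    imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    frames <- lapply(imgs, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m
    })
  }
  if (is.null(timestamps)) {
    sidecar <- paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE),
                      "_timestamps.csv")
    timestamps <- if (file.exists(sidecar))
      utils::read.csv(sidecar)$time_s else seq_along(frames) - 1
  }
  FrameStack(frames, timestamps = timestamps, bitDepth = bitDepth)
}

#' Write a frame stack as a multi-page TIFF with a timestamp sidecar
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param path output TIFF path; timestamps go to
#'   \code{<path>_timestamps.csv}.
#' @return \code{path}, invisibly.
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  scale <- 2^stack@bitDepth - 1
  imgs <- lapply(seq_len(length(stack)),
                 function(i) stack@frames[, , i] / scale)
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  utils::write.csv(data.frame(time_s = stack@timestamps),
                   paste0(sub("\\.tiff?$", "", path, ignore.case = TRUE),
                          "_timestamps.csv"),
                   row.names = FALSE)
  invisible(path)
}
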