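#' Acquisition metadata for a time-lapse movie
#'
#' Bundles the timing and geometry information every downstream computation
#' needs: the frame interval, the physical pixel size, and how many frames
#' were acquired before laser damage. The first post-damage frame is frame
#' `n_predamage + 1` (1-based) and is assigned time 0; pre-damage frames have
#' negative times. Pixel size is never inferred from image data and must be
#' supplied explicitly.
#'
#' @param frame_interval Seconds per frame, strictly positive.
#' @param pixel_size Micrometres per pixel, strictly positive.
#' @param n_predamage Number of frames acquired before damage (integer >= 1).
#'   Equivalently the 0-based index of the first post-damage frame.
#' @return An object of class `acq_meta`.
#' @examples
#' meta <- acq_meta(frame_interval = 0.5, pixel_size = 0.11, n_predamage = 10)
#' frame_times(meta, 20)
#' @export
acq_meta <- function(frame_interval, pixel_size, n_predamage) {
  stopifnot(is.numeric(frame_interval), length(frame_interval) == 1L,
            is.finite(frame_interval), frame_interval > 0)
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L,
            is.finite(pixel_size), pixel_size > 0)
  n_predamage <- as.integer(n_predamage)
  stopifnot(length(n_predamage) == 1L, !is.na(n_predamage), n_predamage >= 1L)
  structure(
    list(frame_interval = as.numeric(frame_interval),
         pixel_size = as.numeric(pixel_size),
         n_predamage = n_predamage),
    class = "acq_meta"
  )
}

#' @export
print.acq_meta <- function(x, ...) {
  cat(sprintf(
    "Acquisition: %.4g s/frame, %.4g um/px, %d pre-damage frame(s)\n",
    x$frame_interval, x$pixel_size, x$n_predamage))
  invisible(x)
}

#' Time axis for a movie
#'
#' Times are measured from the moment of damage: frame `n_predamage + 1`
#' (the first post-damage frame) is t = 0, pre-damage frames are negative.
#'
#' @param meta An [acq_meta()] object.
#' @param n_frames Number of frames.
#' @return Numeric vector of length `n_frames`, in seconds.
#' @export
frame_times <- function(meta, n_frames) {
  stopifnot(inherits(meta, "acq_meta"), n_frames >= 1)
  (seq_len(n_frames) - 1L - meta$n_predamage) * meta$frame_interval
}

#' Rectangular region of interest
#'
#' Pixel rectangles use 0-based, half-open conventions:
#' `[x0, x0 + width) x [y0, y0 + height)`, with x running along columns and
#' y along rows. This makes pixel accounting unambiguous when converting to
#' R's 1-based matrix indices (see [roi_rows()] / [roi_cols()]).
#'
#' @param x0,y0 Top-left pixel (0-based integers, >= 0).
#' @param width,height Extent in pixels; `width * height >= 1`.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(x0, y0, width, height) {
  v <- vapply(list(x0, y0, width, height), function(z) {
    z <- as.integer(z)
    stopifnot(length(z) == 1L, !is.na(z))
    z
  }, integer(1))
  stopifnot(v[1] >= 0L, v[2] >= 0L, v[3] >= 1L, v[4] >= 1L)
  structure(list(x0 = v[1], y0 = v[2], width = v[3], height = v[4]),
            class = "rect_roi")
}

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("ROI [%d, %d) x [%d, %d)  (%d x %d px)\n",
              x$x0, x$x0 + x$width, x$y0, x$y0 + x$height,
              x$width, x$height))
  invisible(x)
}

#' @rdname rect_roi
#' @param roi A `rect_roi`.
#' @export
roi_rows <- function(roi) (roi$y0 + 1L):(roi$y0 + roi$height)

#' @rdname rect_roi
#' @export
roi_cols <- function(roi) (roi$x0 + 1L):(roi$x0 + roi$width)

# stop() unless the ROI lies fully inside an H x W frame
check_roi_in_frame <- function(roi, dim_hw) {
  if (roi$y0 + roi$height > dim_hw[1] || roi$x0 + roi$width > dim_hw[2])
    stop(sprintf("ROI [%d,%d)x[%d,%d) exceeds frame bounds %dx%d",
                 roi$x0, roi$x0 + roi$width, roi$y0, roi$y0 + roi$height,
                 dim_hw[1], dim_hw[2]))
  invisible(TRUE)
}

#' Nucleus mask
#'
#' A boolean H x W mask of the nucleus pixels used for the whole-nucleus mean
#' that drives photobleaching correction. If a damage ROI is supplied, the
#' mask is expected to contain it; a violation produces a warning (not an
#' error), since a rectangle chosen to include some undamaged area may touch
#' the nuclear boundary.
#'
#' @param mask Logical matrix (H x W); must contain at least one `TRUE` pixel.
#' @param damage_roi Optional [rect_roi()] that should lie within the mask.
#' @return An object of class `nucleus_mask` with an `area` field (pixels).
#' @export
nucleus_mask <- function(mask, damage_roi = NULL) {
  stopifnot(is.matrix(mask), is.logical(mask))
  area <- sum(mask)
  if (area < 1L) stop("nucleus mask is empty")
  if (!is.null(damage_roi)) {
    check_roi_in_frame(damage_roi, dim(mask))
    if (!all(mask[roi_rows(damage_roi), roi_cols(damage_roi)]))
      warning("damage ROI is not fully contained in the nucleus mask")
  }
  structure(list(mask = mask, area = area), class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("Nucleus mask %dx%d, area %d px\n",
              nrow(x$mask), ncol(x$mask), x$area))
  invisible(x)
}

#' Elliptical nucleus mask
#'
#' Convenience constructor for the synthetic generator and for ROI configs
#' that describe the nucleus as an ellipse. Pixel centres at 0-based integer
#' coordinates are tested against the ellipse equation.
#'
#' @param height,width Frame dimensions in pixels.
#' @param centre Numeric `(x, y)` centre in 0-based pixel coordinates.
#' @param semiaxes Numeric `(a, b)` semi-axes in pixels (x then y).
#' @param damage_roi Optional [rect_roi()] passed to [nucleus_mask()].
#' @return A `nucleus_mask`.
#' @export
ellipse_mask <- function(height, width, centre, semiaxes, damage_roi = NULL) {
  stopifnot(length(centre) == 2L, length(semiaxes) == 2L, all(semiaxes > 0))
  x <- matrix(rep(0:(width - 1L), each = height), nrow = height)
  y <- matrix(rep(0:(height - 1L), times = width), nrow = height)
  m <- ((x - centre[1]) / semiaxes[1])^2 + ((y - centre[2]) / semiaxes[2])^2 <= 1
  nucleus_mask(m, damage_roi = damage_roi)
}
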