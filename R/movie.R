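#' Single-channel time-lapse movie
#'
#' Frames are stored as an `H x W x T` numeric array (rows = y, columns = x,
#' third dimension = time), all intensities finite and non-negative. At least
#' two frames are required and the damage frame must lie strictly inside the
#' series.
#'
#' @param frames Numeric `H x W x T` array, or a list of `H x W` matrices.
#' @param meta An [acq_meta()] object.
#' @param channel_label Free-text channel name (e.g. `"green"`).
#' @return An object of class `timelapse_movie`.
#' @export
timelapse_movie <- function(frames, meta, channel_label = "") {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(d[1], d[2], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  storage.mode(frames) <- "double"
  if (dim(frames)[3] < 2L) stop("too few frames: a movie needs at least 2")
  if (!all(is.finite(frames))) stop("movie contains non-finite intensities")
  if (min(frames) < 0) stop("movie contains negative intensities")
  stopifnot(inherits(meta, "acq_meta"))
  if (meta$n_predamage >= dim(frames)[3])
    stop("damage frame lies at or beyond the end of the movie")
  structure(
    list(frames = frames, meta = meta,
         channel_label = as.character(channel_label)),
    class = "timelapse_movie"
  )
}

#' @export
print.timelapse_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Time-lapse movie%s: %d frames of %dx%d px, %.4g s interval (%.4g s total)\n",
              if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]") else "",
              d[3], d[1], d[2], x$meta$frame_interval,
              d[3] * x$meta$frame_interval))
  invisible(x)
}

#' @export
dim.timelapse_movie <- function(x) dim(x$frames)

n_frames <- function(movie) dim(movie$frames)[3]

#' Read a multi-page TIFF stack as a time-lapse movie
#'
#' Supports 8/16-bit unsigned integer and 32-bit float TIFF (plain,
#' OME-TIFF or ImageJ-TIFF page organisation). Integer stacks are read
#' bit-exactly (stored integers promoted to double); float stacks keep their
#' native values.
#'
#' @param path Path to a readable multi-page TIFF.
#' @param meta An [acq_meta()] object describing the acquisition.
#' @param channel_label Channel name attached to the movie.
#' @return A [timelapse_movie()].
#' @export
read_movie <- function(path, meta, channel_label = "") {
  if (!file.exists(path)) stop("cannot read movie: no such file: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE)  # float TIFF
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("too few frames: stack has ", length(pages),
                               " page(s), need at least 2")
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # greyscale stored with channels
    p
  })
  timelapse_movie(pages, meta, channel_label)
}

#' Write a movie as a 16-bit multi-page TIFF
#'
#' Values are rounded and clipped to `[0, 2^bits - 1]` camera counts. For
#' integer-valued movies within range the write/read round trip is bit-exact.
#'
#' @param movie A [timelapse_movie()] (or plain `H x W x T` array).
#' @param path Output path.
#' @param bits Bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, bits = 16L) {
  frames <- if (inherits(movie, "timelapse_movie")) movie$frames else movie
  stopifnot(bits %in% c(8L, 16L))
  top <- 2^bits - 1
  pages <- lapply(seq_len(dim(frames)[3]), function(t) {
    m <- pmin(pmax(round(frames[, , t]), 0), top)
    m / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# dimension along which a split-view layout divides the chip
split_axis <- function(layout = c("left-right", "top-bottom")) {
  layout <- match.arg(layout)
  if (layout == "left-right") 2L else 1L
}

# raw (unaligned) halves of every frame; drops last row/col of the larger
# half when the split dimension is odd (with a warning)
split_halves <- function(frames, layout) {
  ax <- split_axis(layout)
  n <- dim(frames)[ax]
  h <- n %/% 2L
  if (n %% 2L == 1L)
    warning(sprintf("odd split dimension (%d px): dropping the last %s of the larger half",
                    n, if (ax == 2L) "column" else "row"))
  second <- (h + 1L):(2L * h)  # drops the trailing row/col of the larger half
  if (ax == 2L) {
    list(first = frames[, 1:h, , drop = FALSE],
         second = frames[, second, , drop = FALSE])
  } else {
    list(first = frames[1:h, , , drop = FALSE],
         second = frames[second, , , drop = FALSE])
  }
}

#' Split a split-view movie into two aligned channels
#'
#' Emission splitters project two colour channels onto the two halves of one
#' camera chip; the second half is typically displaced by a fixed integer
#' offset. The second half is translated by `offset = c(dx, dy)` so that
#' homologous pixels align, then both channels are cropped to the common
#' valid region (shape reduced by `|dx|` columns and `|dy|` rows).
#'
#' The convention: if the second half's content equals the first half's
#' translated by `(dx, dy)` (i.e. `second(x, y) = first(x - dx, y - dy)`),
#' then splitting with `offset = c(dx, dy)` returns pixelwise identical
#' channels. Offsets can be estimated with [estimate_split_offset()].
#'
#' @param movie A [timelapse_movie()] holding split-view frames.
#' @param layout `"left-right"` (default) or `"top-bottom"`.
#' @param offset Integer `(dx, dy)` displacement of the second half.
#' @param labels Channel labels for the first and second half.
#' @return List with components `green` and `red` ([timelapse_movie()]s of
#'   identical shape, metadata copied).
#' @export
split_channels <- function(movie, layout = c("left-right", "top-bottom"),
                           offset = c(0L, 0L),
                           labels = c("green", "red")) {
  layout <- match.arg(layout)
  stopifnot(length(offset) == 2L, offset == round(offset))
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  halves <- split_halves(movie$frames, layout)
  d <- dim(halves$first)
  h <- d[1]; w <- d[2]
  if (abs(dx) >= w || abs(dy) >= h)
    stop(sprintf("offset (%d, %d) exceeds half-frame size %dx%d", dx, dy, h, w))
  # first half sampled at (x, y); second at (x + dx, y + dy)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  ys <- max(1L, 1L - dy):min(h, h - dy)
  a <- halves$first[ys, xs, , drop = FALSE]
  b <- halves$second[ys + dy, xs + dx, , drop = FALSE]
  list(
    green = timelapse_movie(a, movie$meta, labels[1]),
    red   = timelapse_movie(b, movie$meta, labels[2]),
    # 0-based origin of the cropped region within the original half, so ROI
    # coordinates defined on the full half can be shifted into the output
    crop_origin = c(x = xs[1] - 1L, y = ys[1] - 1L)
  )
}

#' Compose two channels into one split-view stack
#'
#' Inverse of [split_channels()] up to the fill border: the second channel is
#' translated by `+offset` before being placed on its half of the chip, so
#' that `split_channels(compose, offset)` recovers both channels on the
#' overlap region exactly.
#'
#' @param green,red [timelapse_movie()]s of identical shape.
#' @inheritParams split_channels
#' @param fill Value used for border pixels exposed by the translation.
#' @return A [timelapse_movie()] of the composed frames.
#' @export
compose_splitview <- function(green, red, layout = c("left-right", "top-bottom"),
                              offset = c(0L, 0L), fill = 0) {
  layout <- match.arg(layout)
  stopifnot(identical(dim(green$frames), dim(red$frames)))
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  d <- dim(red$frames); h <- d[1]; w <- d[2]; T <- d[3]
  shifted <- array(fill, dim = d)
  xs <- max(1L, 1L + dx):min(w, w + dx)   # destination columns
  ys <- max(1L, 1L + dy):min(h, h + dy)
  shifted[ys, xs, ] <- red$frames[ys - dy, xs - dx, , drop = FALSE]
  frames <- if (layout == "left-right") {
    out <- array(0, dim = c(h, 2L * w, T))
    out[, 1:w, ] <- green$frames; out[, (w + 1L):(2L * w), ] <- shifted
    out
  } else {
    out <- array(0, dim = c(2L * h, w, T))
    out[1:h, , ] <- green$frames; out[(h + 1L):(2L * h), , ] <- shifted
    out
  }
  timelapse_movie(frames, green$meta, "split-view")
}

#' Estimate the integer offset between split-view halves
#'
#' Exhaustive search over integer shifts within `±max_shift`, maximizing the
#' normalized cross-correlation (Pearson) between the overlapping parts of
#' the two halves of a pre-damage reference frame. Ties are broken toward
#' the smaller `|shift|` (Euclidean), then smaller `dx`, then smaller `dy`.
#'
#' @param movie A split-view [timelapse_movie()].
#' @param layout `"left-right"` or `"top-bottom"`.
#' @param reference_frame 1-based frame index; must be pre-damage
#'   (`<= n_predamage`), since post-damage frames differ between channels.
#' @param max_shift Search radius in pixels.
#' @return Integer vector `c(dx, dy)` suitable for [split_channels()].
#' @export
estimate_split_offset <- function(movie, layout = c("left-right", "top-bottom"),
                                  reference_frame = 1L, max_shift = 10L) {
  layout <- match.arg(layout)
  reference_frame <- as.integer(reference_frame)
  if (reference_frame > movie$meta$n_predamage)
    stop("reference_frame must be a pre-damage frame (<= n_predamage)")
  halves <- suppressWarnings(split_halves(movie$frames, layout))
  A <- halves$first[, , reference_frame]
  B <- halves$second[, , reference_frame]
  h <- nrow(A); w <- ncol(A)
  if (stats::sd(A) == 0 && stats::sd(B) == 0)
    stop("both halves are constant: alignment undefined")
  shifts <- expand.grid(dx = -max_shift:max_shift, dy = -max_shift:max_shift)
  score <- vapply(seq_len(nrow(shifts)), function(i) {
    dx <- shifts$dx[i]; dy <- shifts$dy[i]
    xs <- max(1L, 1L - dx):min(w, w - dx)
    ys <- max(1L, 1L - dy):min(h, h - dy)
    a <- A[ys, xs]; b <- B[ys + dy, xs + dx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(as.vector(a), as.vector(b))
  }, numeric(1))
  if (!any(is.finite(score)))
    stop("all candidate overlaps have zero variance: alignment undefined")
  best <- max(score, na.rm = TRUE)
  cand <- which(score >= best - 1e-12)
  ord <- order(shifts$dx[cand]^2 + shifts$dy[cand]^2,
               shifts$dx[cand], shifts$dy[cand])
  i <- cand[ord[1]]
  c(dx = shifts$dx[i], dy = shifts$dy[i])
}
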