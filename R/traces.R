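#' Median of the n brightest pixels ("medMax")
#'
#' A noise-robust peak statistic for the damage region: the single maximum is
#' dominated by residual salt-and-pepper noise even after bandpass filtering,
#' while the plain mean is diluted by the deliberately included undamaged
#' area. The median of the 20 brightest pixels tracks the peak without either
#' failing mode. If fewer than `n` values are available, the median of all of
#' them is returned with a warning. The median of an even count is the
#' midpoint of the two central order statistics.
#'
#' @param values Numeric vector of pixel intensities (non-empty).
#' @param n How many of the largest values to keep (default 20).
#' @return A single numeric value.
#' @export
med_max <- function(values, n = 20L) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("med_max: empty input")
  if (length(values) < n) {
    warning(sprintf("med_max: only %d values for top-%d statistic; using all",
                    length(values), n))
    n <- length(values)
  }
  top <- sort(values, decreasing = TRUE)[seq_len(n)]
  stats::median(top)
}

#' Extract a damage-site intensity trace from a movie
#'
#' Per frame: the damage-ROI medMax and the whole-nucleus mean, computed on
#' the DoG-filtered frame by default (set `use_dog = FALSE` for raw pixels;
#' `raw_nucleus = TRUE` uses the unfiltered nucleus mean while keeping the
#' filtered ROI statistic). The unfiltered pre-damage ROI medMax is averaged
#' into `i0_raw`, the initial fluorescence intensity in camera counts used
#' for intensity-based cell selection.
#'
#' @param movie A [timelapse_movie()].
#' @param damage A [rect_roi()] covering the stripe plus a small margin of
#'   undamaged nucleus.
#' @param nucleus A [nucleus_mask()] (or logical matrix).
#' @param use_dog Apply the DoG bandpass before measuring (default `TRUE`).
#' @param dog A [dog_params()]; defaults to the standard scales at the
#'   movie's pixel size.
#' @param n_top Top-pixel count for [med_max()].
#' @param raw_nucleus Use the unfiltered nucleus mean for the bleach
#'   reference.
#' @return An object of class `intensity_trace` with fields `time_s`,
#'   `raw_medmax`, `nucleus_mean`, `i0_raw`, `meta`, `channel_label`.
#' @export
extract_trace <- function(movie, damage, nucleus,
                          use_dog = TRUE,
                          dog = dog_params(pixel_size = movie$meta$pixel_size),
                          n_top = 20L, raw_nucleus = FALSE) {
  stopifnot(inherits(movie, "timelapse_movie"), inherits(damage, "rect_roi"))
  if (is.matrix(nucleus)) nucleus <- nucleus_mask(nucleus, damage)
  stopifnot(inherits(nucleus, "nucleus_mask"))
  d <- dim(movie$frames)
  check_roi_in_frame(damage, d[1:2])
  stopifnot(identical(dim(nucleus$mask), d[1:2]))
  T <- d[3]
  rows <- roi_rows(damage); cols <- roi_cols(damage)

  filtered <- if (use_dog) dog_filter_movie(movie, dog) else movie$frames
  raw_medmax <- numeric(T); nucleus_mean <- numeric(T); raw_mm <- numeric(T)
  for (t in seq_len(T)) {
    ff <- filtered[, , t]
    raw_medmax[t] <- med_max(ff[rows, cols], n_top)
    nucleus_mean[t] <- if (raw_nucleus) mean(movie$frames[, , t][nucleus$mask])
                       else mean(ff[nucleus$mask])
    raw_mm[t] <- if (use_dog) med_max(movie$frames[rows, cols, t], n_top)
                 else raw_medmax[t]
  }
  if (any(nucleus_mean <= 0))
    stop("nucleus mean <= 0 at frame(s) ",
         paste(utils::head(which(nucleus_mean <= 0), 5), collapse = ", "),
         ": empty mask or over-filtering")
  pre <- seq_len(movie$meta$n_predamage)
  structure(list(
    time_s = frame_times(movie$meta, T),
    raw_medmax = raw_medmax,
    nucleus_mean = nucleus_mean,
    i0_raw = mean(raw_mm[pre]),
    meta = movie$meta,
    channel_label = movie$channel_label,
    use_dog = use_dog
  ), class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace%s: %d frames, i0_raw = %.4g counts\n",
              if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]") else "",
              length(x$time_s), x$i0_raw))
  invisible(x)
}

#' Photobleaching correction
#'
#' Divides the damage-site medMax by the whole-nucleus mean at each frame,
#' cancelling global photobleaching (and any multiplicative gain).
#'
#' @param trace An [extract_trace()] result.
#' @return Numeric vector `corrected[t] = raw_medmax[t] / nucleus_mean[t]`.
#' @export
bleach_correct <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (any(trace$nucleus_mean <= 0))
    stop("non-positive nucleus mean: cannot bleach-correct")
  trace$raw_medmax / trace$nucleus_mean
}

#' Three-point temporal smoothing
#'
#' Each interior time point is averaged with its immediate predecessor and
#' successor; endpoints use the mean of the two available terms. Disabled in
#' the fast-imaging regime, where a 3-frame window would blur sub-second
#' kinetics.
#'
#' @param x Numeric series (length >= 1).
#' @return Smoothed series of the same length.
#' @export
smooth3 <- function(x) {
  T <- length(x)
  if (T <= 1L) return(x)
  if (T == 2L) return(rep(mean(x), 2L))
  s <- (c(x[-1], 0) + x + c(0, x[-T])) / 3
  s[1] <- (x[1] + x[2]) / 2
  s[T] <- (x[T - 1] + x[T]) / 2
  s
}

# pre-damage baseline of a corrected series
baseline_i0 <- function(corrected, meta) {
  pre <- seq_len(meta$n_predamage)
  if (length(corrected) < meta$n_predamage)
    stop("series shorter than the pre-damage window")
  mean(corrected[pre])
}

#' Relative fluorescence intensity (RFI)
#'
#' Normalizes the corrected series against the initial intensity `I0`, the
#' mean of the corrected values over all pre-damage frames; by construction
#' the pre-damage mean of RFI is exactly 1.
#'
#' @param corrected Bleach-corrected series (see [bleach_correct()]).
#' @param meta An [acq_meta()].
#' @return List with `rfi` (series) and `i0` (scalar baseline).
#' @export
rfi_curve <- function(corrected, meta) {
  i0 <- baseline_i0(corrected, meta)
  if (!is.finite(i0) || i0 <= 0) stop("pre-damage baseline i0 <= 0")
  list(rfi = corrected / i0, i0 = i0)
}

#' Background-subtracted intensity change
#'
#' `delta[t] = corrected[t] - i0`; the additive counterpart of RFI
#' (`delta = i0 * (rfi - 1)`).
#'
#' @inheritParams rfi_curve
#' @return Numeric series.
#' @export
delta_intensity <- function(corrected, meta) {
  corrected - baseline_i0(corrected, meta)
}

#' Fraction of maximum recruitment (FMR)
#'
#' Rescales RFI so the pre-damage baseline maps to 0 and the post-damage
#' maximum to 1: `fmr = (rfi - 1) / (max_rfi - 1)`. FMR describes kinetics
#' free of amplitude, and is invariant to any positive gain on the raw
#' intensities. Values at noisy pre-damage frames may dip below 0 and are
#' reported as-is. When no recruitment is detected
#' (`max_rfi <= 1 + epsilon`) the curve is undefined and flagged.
#'
#' @param rfi RFI series (pre-damage mean 1).
#' @param meta An [acq_meta()].
#' @param epsilon Minimal detectable excess over baseline (default 1e-6).
#' @return List with `fmr` (series or `NULL`), `max_rfi`, `t_max` (seconds),
#'   and `defined` (logical).
#' @export
fmr_curve <- function(rfi, meta, epsilon = 1e-6) {
  T <- length(rfi)
  post <- (meta$n_predamage + 1L):T
  max_rfi <- max(rfi[post])
  tm_idx <- post[which.max(rfi[post])]  # earliest frame on ties
  times <- frame_times(meta, T)
  if (max_rfi <= 1 + epsilon) {
    return(list(fmr = NULL, max_rfi = max_rfi, t_max = NA_real_,
                defined = FALSE, reason = "no recruitment detected"))
  }
  list(fmr = (rfi - 1) / (max_rfi - 1), max_rfi = max_rfi,
       t_max = times[tm_idx], defined = TRUE, reason = NULL)
}

#' Time to half-maximal recruitment (t50)
#'
#' The time, in seconds from damage, of the first post-damage frame whose
#' FMR reaches 0.5. `interpolate = TRUE` instead places the crossing by
#' linear interpolation between the bracketing frames. Returns `NA` when
#' the curve never reaches 0.5.
#'
#' @param fmr FMR series (see [fmr_curve()]).
#' @param meta An [acq_meta()].
#' @param interpolate Linear interpolation between bracketing frames.
#' @return Seconds, or `NA_real_`.
#' @export
time_to_half_max <- function(fmr, meta, interpolate = FALSE) {
  if (is.null(fmr)) return(NA_real_)
  T <- length(fmr)
  post <- (meta$n_predamage + 1L):T
  hit <- post[which(fmr[post] >= 0.5)]
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1]
  times <- frame_times(meta, T)
  if (!interpolate || i == post[1] || fmr[i - 1] >= 0.5) return(times[i])
  frac <- (0.5 - fmr[i - 1]) / (fmr[i] - fmr[i - 1])
  times[i - 1] + frac * meta$frame_interval
}

#' Scalar descriptors of a recruitment curve
#'
#' @param rfi RFI series.
#' @param fmr FMR series (or `NULL` when undefined).
#' @param meta An [acq_meta()].
#' @param interpolate_t50 Passed to [time_to_half_max()].
#' @return List with `max_rfi`, `t_max` (seconds; earliest frame on ties),
#'   `t50` (seconds or `NA`) and `final_fmr` (FMR at the last frame).
#' @export
curve_stats <- function(rfi, fmr, meta, interpolate_t50 = FALSE) {
  T <- length(rfi)
  post <- (meta$n_predamage + 1L):T
  times <- frame_times(meta, T)
  list(max_rfi = max(rfi[post]),
       t_max = times[post[which.max(rfi[post])]],
       t50 = time_to_half_max(fmr, meta, interpolate_t50),
       final_fmr = if (is.null(fmr)) NA_real_ else fmr[T])
}

#' Normalized recruitment curve for one trace
#'
#' Runs the fixed normalization pipeline on an extracted trace:
#' bleach correction, optional three-point smoothing, RFI and delta-I
#' normalization, FMR rescaling, and scalar kinetics.
#'
#' @param trace An [extract_trace()] result.
#' @param smooth Apply [smooth3()] (default `TRUE`; use `FALSE` in the
#'   fast-imaging regime).
#' @param interpolate_t50 Linear interpolation for the half-max crossing.
#' @param epsilon Recruitment-detection threshold for [fmr_curve()].
#' @return An object of class `recruitment_curve` with fields `time_s`,
#'   `corrected`, `rfi`, `delta`, `fmr`, `i0`, `i0_raw`, `max_rfi`, `t_max`,
#'   `t50`, `final_fmr`, `defined`, `smooth`.
#' @export
recruitment_curve <- function(trace, smooth = TRUE, interpolate_t50 = FALSE,
                              epsilon = 1e-6) {
  corrected <- bleach_correct(trace)
  if (smooth) corrected <- smooth3(corrected)
  r <- rfi_curve(corrected, trace$meta)
  fm <- fmr_curve(r$rfi, trace$meta, epsilon)
  st <- curve_stats(r$rfi, fm$fmr, trace$meta, interpolate_t50)
  structure(list(
    time_s = trace$time_s, corrected = corrected,
    rfi = r$rfi, delta = corrected - r$i0, fmr = fm$fmr,
    i0 = r$i0, i0_raw = trace$i0_raw,
    max_rfi = st$max_rfi, t_max = st$t_max, t50 = st$t50,
    final_fmr = st$final_fmr,
    defined = fm$defined, reason = fm$reason,
    smooth = smooth, meta = trace$meta,
    channel_label = trace$channel_label
  ), class = "recruitment_curve")
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf("Recruitment curve%s: max RFI %.3g at %.3g s, t50 %s, final FMR %s%s\n",
              if (nzchar(x$channel_label)) paste0(" [", x$channel_label, "]") else "",
              x$max_rfi, x$t_max,
              if (is.na(x$t50)) "undefined" else sprintf("%.3g s", x$t50),
              if (is.na(x$final_fmr)) "undefined" else sprintf("%.3g", x$final_fmr),
              if (x$defined) "" else paste0(" (", x$reason, ")")))
  invisible(x)
}

#' Paired-channel record for one cell
#'
#' Bundles the green and red traces and curves of one cell together with its
#' nucleus area. Both channels must share frame count and acquisition
#' metadata.
#'
#' @param cell_id Identifier (character or integer).
#' @param green,red [intensity_trace()]s (see [extract_trace()]).
#' @param nucleus_area Nucleus area in pixels.
#' @param smooth,interpolate_t50 Passed to [recruitment_curve()].
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(cell_id, green, red, nucleus_area,
                        smooth = TRUE, interpolate_t50 = FALSE) {
  stopifnot(inherits(green, "intensity_trace"), inherits(red, "intensity_trace"))
  if (length(green$time_s) != length(red$time_s))
    stop("channels differ in frame count")
  if (!isTRUE(all.equal(green$meta$frame_interval, red$meta$frame_interval)))
    stop("channels differ in frame interval")
  meta <- green$meta
  structure(list(
    cell_id = as.character(cell_id),
    green = list(trace = green,
                 curve = recruitment_curve(green, smooth, interpolate_t50)),
    red = list(trace = red,
               curve = recruitment_curve(red, smooth, interpolate_t50)),
    nucleus_area_px = as.numeric(nucleus_area),
    nucleus_area_um2 = as.numeric(nucleus_area) * meta$pixel_size^2,
    meta = meta,
    qc_pass = NA, qc_reason = NA_character_
  ), class = "cell_record")
}

#' @export
print.cell_record <- function(x, ...) {
  cat(sprintf("Cell %s: nucleus %.0f px (%.1f um^2), green t50 %s, red t50 %s\n",
              x$cell_id, x$nucleus_area_px, x$nucleus_area_um2,
              if (is.na(x$green$curve$t50)) "NA" else sprintf("%.3g s", x$green$curve$t50),
              if (is.na(x$red$curve$t50)) "NA" else sprintf("%.3g s", x$red$curve$t50)))
  invisible(x)
}

#' Analyze both channels of a simulated (or split) movie pair
#'
#' Convenience wrapper: extracts traces for both channels with a shared
#' damage ROI and nucleus mask and assembles a [cell_record()].
#'
#' @param cell_id Identifier.
#' @param green,red [timelapse_movie()]s.
#' @param damage A [rect_roi()].
#' @param nucleus A [nucleus_mask()] or logical matrix.
#' @param smooth,interpolate_t50 Passed to [recruitment_curve()].
#' @param use_dog,dog,n_top Passed to [extract_trace()].
#' @return A [cell_record()].
#' @export
analyze_cell <- function(cell_id, green, red, damage, nucleus,
                         smooth = TRUE, interpolate_t50 = FALSE,
                         use_dog = TRUE,
                         dog = dog_params(pixel_size = green$meta$pixel_size),
                         n_top = 20L) {
  if (is.matrix(nucleus)) nucleus <- nucleus_mask(nucleus, damage)
  gt <- extract_trace(green, damage, nucleus, use_dog = use_dog, dog = dog,
                      n_top = n_top)
  rt <- extract_trace(red, damage, nucleus, use_dog = use_dog, dog = dog,
                      n_top = n_top)
  cell_record(cell_id, gt, rt, nucleus$area, smooth = smooth,
              interpolate_t50 = interpolate_t50)
}
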