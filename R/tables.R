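#' Write per-cell traces to a long-format CSV
#'
#' One row per cell, channel and frame with the raw statistic, the bleach
#' reference, and the normalized series. Numbers are written at full
#' precision (15 significant digits) so the file round-trips losslessly.
#'
#' @param records List of [cell_record()]s sharing frame count and interval.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(records, path) {
  if (length(records) > 0L) {
    Ts <- vapply(records, function(r) length(r$green$trace$time_s), integer(1))
    dts <- vapply(records, function(r) r$meta$frame_interval, numeric(1))
    if (length(unique(Ts)) > 1L || length(unique(dts)) > 1L)
      stop("records differ in frame count or interval")
  }
  rows <- lapply(records, function(rec) {
    do.call(rbind, lapply(c("green", "red"), function(ch) {
      tr <- rec[[ch]]$trace; cv <- rec[[ch]]$curve
      T <- length(tr$time_s)
      data.frame(cell_id = rec$cell_id, channel = ch, frame = seq_len(T),
                 time_s = tr$time_s, raw_medmax = tr$raw_medmax,
                 nucleus_mean = tr$nucleus_mean, corrected = cv$corrected,
                 rfi = cv$rfi,
                 fmr = if (is.null(cv$fmr)) rep(NA_real_, T) else cv$fmr,
                 stringsAsFactors = FALSE)
    }))
  })
  df <- if (length(rows) == 0L) {
    data.frame(cell_id = character(), channel = character(),
               frame = integer(), time_s = numeric(), raw_medmax = numeric(),
               nucleus_mean = numeric(), corrected = numeric(),
               rfi = numeric(), fmr = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a traces CSV written by [write_traces()]
#'
#' @param path CSV path.
#' @return Data frame in the long trace format.
#' @export
read_traces <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(cell_id = "character"))
}

#' Write the per-cell summary table
#'
#' One row per cell with initial intensities, nucleus area and scalar
#' kinetics for both channels; the companion of the long traces file.
#'
#' @param records List of [cell_record()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(rec) {
    data.frame(
      cell_id = rec$cell_id,
      nucleus_area_px = rec$nucleus_area_px,
      nucleus_area_um2 = rec$nucleus_area_um2,
      green_i0_raw = rec$green$trace$i0_raw,
      red_i0_raw = rec$red$trace$i0_raw,
      green_i0 = rec$green$curve$i0,
      red_i0 = rec$red$curve$i0,
      green_max_rfi = rec$green$curve$max_rfi,
      red_max_rfi = rec$red$curve$max_rfi,
      green_t50 = rec$green$curve$t50,
      red_t50 = rec$red$curve$t50,
      green_final_fmr = rec$green$curve$final_fmr,
      red_final_fmr = rec$red$curve$final_fmr,
      stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- data.frame(cell_id = character())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rebuild cell records from traces and cell tables
#'
#' Inverse of [write_traces()] + [write_cells()] for the analysis stage:
#' reconstructs [cell_record()]s (recomputing the normalization pipeline
#' from the stored raw series) without needing the original movies.
#'
#' @param traces Data frame from [read_traces()] (or a path).
#' @param cells Data frame from the cells CSV (or a path).
#' @param meta An [acq_meta()] matching the acquisition.
#' @param smooth Smoothing toggle used when the traces were extracted.
#' @return List of [cell_record()]s.
#' @export
records_from_tables <- function(traces, cells, meta, smooth = TRUE) {
  if (is.character(traces)) traces <- read_traces(traces)
  if (is.character(cells))
    cells <- utils::read.csv(cells, stringsAsFactors = FALSE,
                             colClasses = c(cell_id = "character"))
  ids <- unique(traces$cell_id)
  lapply(ids, function(id) {
    ti <- traces[traces$cell_id == id, ]
    ci <- cells[cells$cell_id == id, ]
    mk_trace <- function(ch) {
      tc <- ti[ti$channel == ch, ]
      tc <- tc[order(tc$frame), ]
      structure(list(
        time_s = tc$time_s, raw_medmax = tc$raw_medmax,
        nucleus_mean = tc$nucleus_mean,
        i0_raw = if (nrow(ci)) ci[[paste0(ch, "_i0_raw")]] else NA_real_,
        meta = meta, channel_label = ch, use_dog = NA
      ), class = "intensity_trace")
    }
    cell_record(id, mk_trace("green"), mk_trace("red"),
                nucleus_area = if (nrow(ci)) ci$nucleus_area_px else NA_real_,
                smooth = smooth)
  })
}
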