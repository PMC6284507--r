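#' Intensity-based cell quality control
#'
#' Cells are selected by their initial fluorescence intensities so that
#' expression levels are comparable across conditions and green-to-red
#' bleed-through stays negligible: the red baseline must exceed the green
#' one, and each channel must fall in its configured window (defaults:
#' green 140-200, red 200-400 counts).
#'
#' @param cells List of [cell_record()]s.
#' @param green_range,red_range Inclusive `c(lo, hi)` windows in counts.
#' @param require_red_gt_green Enforce red i0 > green i0 (default `TRUE`).
#' @param i0 Which initial intensity to gate on: `"raw"` (camera counts,
#'   default) or `"corrected"` (bleach-corrected scale).
#' @return List with `passing` (cell records, with `qc_pass`/`qc_reason`
#'   filled in) and `failing` (data frame `cell_id`, `reason`).
#' @export
qc_filter <- function(cells, green_range = c(140, 200),
                      red_range = c(200, 400),
                      require_red_gt_green = TRUE,
                      i0 = c("raw", "corrected")) {
  i0 <- match.arg(i0)
  get_i0 <- function(cell, ch)
    if (i0 == "raw") cell[[ch]]$trace$i0_raw else cell[[ch]]$curve$i0
  passing <- list(); fail_id <- character(); fail_reason <- character()
  for (cell in cells) {
    g <- get_i0(cell, "green"); r <- get_i0(cell, "red")
    reasons <- character()
    if (g < green_range[1] || g > green_range[2])
      reasons <- c(reasons, "green i0 out of range")
    if (r < red_range[1] || r > red_range[2])
      reasons <- c(reasons, "red i0 out of range")
    if (require_red_gt_green && r <= g)
      reasons <- c(reasons, "red i0 <= green i0")
    if (length(reasons) == 0L) {
      cell$qc_pass <- TRUE; cell$qc_reason <- ""
      passing <- c(passing, list(cell))
    } else {
      fail_id <- c(fail_id, cell$cell_id)
      fail_reason <- c(fail_reason, paste(reasons, collapse = "; "))
    }
  }
  list(passing = passing,
       failing = data.frame(cell_id = fail_id, reason = fail_reason,
                            stringsAsFactors = FALSE))
}

# final FMR per cell for a channel, NA when undefined
final_fmr_of <- function(cells, channel) {
  vapply(cells, function(c) c[[channel]]$curve$final_fmr, numeric(1))
}

#' Rank clustering by final FMR
#'
#' Cells are sorted by their FMR at the last measured time point
#' (descending) and split into `k` contiguous, equally sized rank groups
#' (sizes differ by at most one; larger groups come first). Cluster 1 holds
#' the strongest persistent recruiters; dissociating subpopulations collect
#' in the lower clusters.
#'
#' @param cells List of [cell_record()]s.
#' @param channel `"green"` or `"red"`.
#' @param k Number of clusters (default 4, any k >= 2).
#' @return List with `assignments` (data frame `cell_id`, `final_fmr`,
#'   `cluster`, in rank order) and `ranges` (data frame per cluster:
#'   `cluster`, `n`, `fmr_min`, `fmr_max`).
#' @export
cluster_by_final_fmr <- function(cells, channel = "green", k = 4L) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  ff <- final_fmr_of(cells, channel)
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  ok <- is.finite(ff)
  if (sum(ok) < k)
    stop(sprintf("need at least k = %d cells with defined final FMR, have %d",
                 k, sum(ok)))
  ff <- ff[ok]; ids <- ids[ok]
  ord <- order(-ff)  # descending, stable on ties (radix preserves order)
  n <- length(ff)
  base <- n %/% k; rem <- n %% k
  sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
  cluster <- rep(seq_len(k), times = sizes)
  assignments <- data.frame(cell_id = ids[ord], final_fmr = ff[ord],
                            cluster = cluster, stringsAsFactors = FALSE)
  ranges <- do.call(rbind, lapply(seq_len(k), function(j) {
    v <- assignments$final_fmr[assignments$cluster == j]
    data.frame(cluster = j, n = length(v),
               fmr_min = min(v), fmr_max = max(v))
  }))
  list(assignments = assignments, ranges = ranges)
}

#' Heatmap row order by windowed mean FMR
#'
#' Orders cells by their mean FMR over a frame window (defaults to frames
#' 15-150, i.e. 7.5-75 s at 0.5 s interval), descending, so strong early
#' recruiters sit on top of the heatmap. The window is clamped to the series
#' length with a warning; ties keep the input order (stable).
#'
#' @param cells List of [cell_record()]s.
#' @param channel `"green"` or `"red"`.
#' @param window Inclusive 1-based frame-index window `c(first, last)`.
#' @return Integer permutation of `seq_along(cells)`.
#' @export
heatmap_order <- function(cells, channel = "green", window = c(15L, 150L)) {
  stopifnot(length(cells) >= 1L, length(window) == 2L)
  T <- length(cells[[1]][[channel]]$curve$time_s)
  w <- as.integer(window)
  if (w[2] > T || w[1] < 1L) {
    w <- c(max(1L, w[1]), min(T, w[2]))
    warning(sprintf("heatmap window clamped to frames %d-%d", w[1], w[2]))
  }
  if (w[1] > w[2]) stop("empty heatmap window after clamping")
  m <- vapply(cells, function(c) {
    f <- c[[channel]]$curve$fmr
    if (is.null(f)) -Inf else mean(f[w[1]:w[2]])
  }, numeric(1))
  order(-m)  # radix sort: stable, so ties preserve cell order
}

#' Ordinary least-squares line with descriptive R-squared
#'
#' Simple linear regression as used for the descriptive intensity-kinetics
#' scatters. `R^2 = 1 - SS_res / SS_tot`, defined as 0 for constant `y`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; `x` must vary.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("x is constant: slope undefined")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(x))
}

# shared engine for the scatter analyses: build (x, y) per cell, drop
# cells with undefined y, fit
scatter_fit <- function(ids, x, y, x_name, y_name) {
  ok <- is.finite(x) & is.finite(y)
  excluded <- sum(!ok)
  if (sum(ok) < 3L)
    stop(sprintf("too few cells with defined %s (%d)", y_name, sum(ok)))
  tab <- data.frame(cell_id = ids[ok], x = x[ok], y = y[ok],
                    stringsAsFactors = FALSE)
  names(tab)[2:3] <- c(x_name, y_name)
  list(fit = fit_linear(x[ok], y[ok]), points = tab, n_excluded = excluded)
}

cell_scalar <- function(cells, channel, what) {
  vapply(cells, function(c) {
    cv <- c[[channel]]$curve
    switch(what,
           i0 = cv$i0_raw,
           i0_corrected = cv$i0,
           t50 = cv$t50,
           final_fmr = cv$final_fmr,
           max_rfi = cv$max_rfi,
           nucleus_area = c$nucleus_area_um2,
           stop("unknown scalar: ", what))
  }, numeric(1))
}

#' Initial intensity versus kinetics scatter
#'
#' Regresses a kinetic descriptor (`t50` or `final_fmr`) on the initial
#' fluorescence intensity of the same channel, to detect expression-level
#' artefacts. Cells without a defined descriptor are excluded listwise and
#' counted.
#'
#' @param cells List of [cell_record()]s.
#' @param channel `"green"` or `"red"`.
#' @param y `"t50"` (default) or `"final_fmr"`.
#' @return List with `fit` (see [fit_linear()]), `points` (per-cell table)
#'   and `n_excluded`.
#' @export
intensity_kinetics_scatter <- function(cells, channel = "green",
                                       y = c("t50", "final_fmr")) {
  y <- match.arg(y)
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  scatter_fit(ids, cell_scalar(cells, channel, "i0"),
              cell_scalar(cells, channel, y), "i0", y)
}

#' Cross-channel intensity/kinetics scatter
#'
#' Tests whether the expression level of one protein affects the recruitment
#' kinetics of the other: x is the initial intensity of `x_channel`, y the
#' descriptor of `y_channel`.
#'
#' @inheritParams intensity_kinetics_scatter
#' @param x_channel,y_channel Channel names.
#' @return As [intensity_kinetics_scatter()].
#' @export
cross_correlation_scatter <- function(cells, x_channel = "green",
                                      y_channel = "red",
                                      y = c("t50", "final_fmr")) {
  y <- match.arg(y)
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  scatter_fit(ids, cell_scalar(cells, x_channel, "i0"),
              cell_scalar(cells, y_channel, y),
              paste0("i0_", x_channel), paste0(y, "_", y_channel))
}

#' Nuclear size versus kinetics scatter
#'
#' @inheritParams intensity_kinetics_scatter
#' @return As [intensity_kinetics_scatter()], with x = nucleus area (um^2).
#' @export
nuclear_size_scatter <- function(cells, channel = "green",
                                 y = c("t50", "final_fmr")) {
  y <- match.arg(y)
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  scatter_fit(ids, cell_scalar(cells, channel, "nucleus_area"),
              cell_scalar(cells, channel, y), "nucleus_area_um2", y)
}

#' Single-cell FMR ratio between channels
#'
#' Per cell and frame, the ratio of the numerator channel's FMR to the
#' denominator channel's, averaged across cells with the standard error of
#' the mean. Because FMR hovers around 0 before recruitment, the ratio is
#' masked before `start` post-damage frames and wherever the denominator is
#' below `delta` (default 0.05).
#'
#' @param cells List of [cell_record()]s; both FMR curves must be defined.
#' @param numerator,denominator Channel names (default red / green).
#' @param start First post-damage frame (1-based, >= 1) entering the ratio.
#' @param delta Minimal denominator FMR.
#' @return List with `time_s`, `ratio` (cells x frames matrix, `NA` where
#'   masked), `mean`, `sem`, `n` (per frame).
#' @export
fmr_ratio <- function(cells, numerator = "red", denominator = "green",
                      start = 1L, delta = 0.05) {
  stopifnot(length(cells) >= 1L, start >= 1L)
  keep <- vapply(cells, function(c)
    c[[numerator]]$curve$defined && c[[denominator]]$curve$defined, logical(1))
  if (!any(keep)) stop("no cells with both FMR curves defined")
  cells <- cells[keep]
  meta <- cells[[1]]$meta
  T <- length(cells[[1]][[numerator]]$curve$time_s)
  ratio <- t(vapply(cells, function(c) {
    num <- c[[numerator]]$curve$fmr
    den <- c[[denominator]]$curve$fmr
    r <- num / den
    mask <- seq_len(T) < meta$n_predamage + as.integer(start) | den < delta
    r[mask] <- NA_real_
    r
  }, numeric(T)))
  n <- colSums(!is.na(ratio))
  if (all(n == 0)) stop("denominator below delta everywhere: no unmasked points")
  mean_r <- colMeans(ratio, na.rm = TRUE); mean_r[n == 0] <- NA_real_
  sd_r <- apply(ratio, 2, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 1, sd_r / sqrt(n), NA_real_)
  list(time_s = cells[[1]][[numerator]]$curve$time_s,
       ratio = ratio, mean = mean_r, sem = sem, n = n)
}

#' Mean and SEM recruitment curves across cells
#'
#' @param cells List of [cell_record()]s.
#' @param channel `"green"` or `"red"`.
#' @param quantity `"rfi"` (default) or `"fmr"`.
#' @return List with `time_s`, `mean`, `sem` (sd / sqrt(n)), `n` per frame.
#' @export
mean_sem_curves <- function(cells, channel = "green",
                            quantity = c("rfi", "fmr")) {
  quantity <- match.arg(quantity)
  stopifnot(length(cells) >= 1L)
  T <- length(cells[[1]][[channel]]$curve$time_s)
  m <- t(vapply(cells, function(c) {
    v <- c[[channel]]$curve[[quantity]]
    if (is.null(v)) rep(NA_real_, T) else v
  }, numeric(T)))
  n <- colSums(!is.na(m))
  mean_v <- colMeans(m, na.rm = TRUE); mean_v[n == 0] <- NA_real_
  sd_v <- apply(m, 2, stats::sd, na.rm = TRUE)
  list(time_s = cells[[1]][[channel]]$curve$time_s,
       mean = mean_v, sem = ifelse(n > 1, sd_v / sqrt(n), NA_real_), n = n)
}

#' Paired green/red t50 values
#'
#' @param cells List of [cell_record()]s.
#' @return Data frame `cell_id`, `t50_green`, `t50_red` for cells where both
#'   are defined; the number of excluded cells is attached as attribute
#'   `n_excluded`.
#' @export
t50_scatter <- function(cells) {
  ids <- vapply(cells, function(c) c$cell_id, character(1))
  g <- cell_scalar(cells, "green", "t50")
  r <- cell_scalar(cells, "red", "t50")
  ok <- is.finite(g) & is.finite(r)
  out <- data.frame(cell_id = ids[ok], t50_green = g[ok], t50_red = r[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  out
}
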