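#' Plot a mean +/- SEM recruitment curve
#'
#' @param ms Result of [mean_sem_curves()] (or [fmr_ratio()]).
#' @param ylab Axis label.
#' @param col Line colour.
#' @param add Add to an existing plot.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `ms`.
#' @export
plot_mean_sem <- function(ms, ylab = "mean +/- SEM", col = "darkgreen",
                          add = FALSE, ...) {
  ok <- is.finite(ms$mean)
  if (!add)
    graphics::plot(ms$time_s[ok], ms$mean[ok], type = "l", col = col,
                   xlab = "time from damage (s)", ylab = ylab, ...)
  else
    graphics::lines(ms$time_s[ok], ms$mean[ok], col = col, ...)
  up <- ms$mean + ms$sem; dn <- ms$mean - ms$sem
  ok2 <- ok & is.finite(up)
  graphics::polygon(c(ms$time_s[ok2], rev(ms$time_s[ok2])),
                    c(up[ok2], rev(dn[ok2])), border = NA,
                    col = grDevices::adjustcolor(col, alpha.f = 0.25))
  invisible(ms)
}

#' FMR heatmap across cells
#'
#' Rows are cells (ordered by [heatmap_order()] unless an order is given),
#' columns are frames; blue encodes the lowest FMR, yellow the highest.
#'
#' @param cells List of [cell_record()]s.
#' @param channel `"green"` or `"red"`.
#' @param order Optional row permutation (default: [heatmap_order()]).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix (cells x frames, top row first).
#' @export
plot_fmr_heatmap <- function(cells, channel = "green", order = NULL, ...) {
  if (is.null(order)) order <- heatmap_order(cells, channel)
  T <- length(cells[[1]][[channel]]$curve$time_s)
  m <- t(vapply(cells[order], function(c) {
    f <- c[[channel]]$curve$fmr
    if (is.null(f)) rep(NA_real_, T) else f
  }, numeric(T)))
  pal <- grDevices::colorRampPalette(c("#00008B", "#4169E1", "#2E8B57",
                                       "#FFD700", "#FFFF00"))(255)
  graphics::image(x = cells[[1]][[channel]]$curve$time_s,
                  y = seq_len(nrow(m)), z = t(m)[, rev(seq_len(nrow(m)))],
                  col = pal, xlab = "time from damage (s)", ylab = "cell",
                  ...)
  invisible(m)
}

#' Scatter plot with fitted line
#'
#' @param sc Result of a scatter analysis (e.g.
#'   [intensity_kinetics_scatter()]).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `sc`.
#' @export
plot_scatter_fit <- function(sc, ...) {
  x <- sc$points[[2]]; y <- sc$points[[3]]
  graphics::plot(x, y, pch = 19, col = "grey30",
                 xlab = names(sc$points)[2], ylab = names(sc$points)[3], ...)
  graphics::abline(sc$fit$intercept, sc$fit$slope, col = "firebrick")
  graphics::mtext(sprintf("R^2 = %.2f (n = %d)", sc$fit$r_squared, sc$fit$n),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(sc)
}
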